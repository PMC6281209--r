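#' Read genotypes from a VCF file
#'
#' Parses a VCF v4.x file into a \code{\link{genotype_matrix}}.  Only SNP
#' records are imported: any record whose REF or one of whose ALT alleles
#' is not a single base in \code{A,C,G,T,N} (i.e. insertions/deletions) is
#' skipped.  Multi-allelic SNPs are retained and flagged
#' \code{biallelic = FALSE}; their dosage counts non-reference alleles.
#' Genotypes are diploid dosages: phased (\code{|}) and unphased (\code{/})
#' separators are equivalent, and half-missing calls such as \code{./0}
#' are treated as fully missing because their dosage is undefined.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param min_depth_to_keep if not \code{NULL}, genotypes whose DP is below
#'   this value are set missing (the low-coverage mask; the study protocol
#'   uses 10).  Applied at read time; \code{\link{mask_low_depth}} applies
#'   the same rule to an existing matrix.
#' @param depth_policy what to do when masking is requested but a call has
#'   no DP: \code{"strict"} (default) treats the call as missing, since its
#'   coverage cannot be verified; \code{"lenient"} keeps it.
#'
#' @return a \code{\link{genotype_matrix}} with depths taken from DP
#'   (\code{NA} where DP is absent or \code{.}).
#' @export
read_vcf <- function(path, min_depth_to_keep = NULL,
                     depth_policy = c("strict", "lenient")) {
  depth_policy <- match.arg(depth_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  validate_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- is_snp_allele(ref)
  alt_split <- strsplit(alt, ",", fixed = TRUE)
  snp <- snp & vapply(alt_split, function(a) all(is_snp_allele(a)), logical(1))
  if (!any(snp)) stop("no SNP records in ", path)

  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gt <- gt[snp, , drop = FALSE]
  dp <- dp[snp, , drop = FALSE]

  calls <- t(apply(gt, c(1, 2), gt_to_dosage))
  depths <- t(dp)
  storage.mode(depths) <- "integer"

  ids <- fix[snp, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(
    fix[snp, "CHROM"], ":", fix[snp, "POS"])[is.na(ids) | ids == "."]
  variants <- data.frame(
    chrom = fix[snp, "CHROM"],
    pos = as.integer(fix[snp, "POS"]),
    id = ids,
    ref = ref[snp],
    alt = alt[snp],
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(calls, depths, variants, samples = colnames(gt))
  if (!is.null(min_depth_to_keep)) {
    gm <- mask_low_depth(gm, min_depth = min_depth_to_keep,
                         unknown_depth = depth_policy)
  }
  gm
}

is_snp_allele <- function(a) {
  nchar(a) == 1L & a %in% c("A", "C", "G", "T", "N")
}

# Diploid GT string -> alt-allele dosage; NA when any allele is missing.
gt_to_dosage <- function(g) {
  if (is.na(g) || g == "." || g == "./." || g == ".|.") return(NA_integer_)
  al <- strsplit(g, "[/|]")[[1]]
  if (length(al) != 2L || any(al == ".")) return(NA_integer_)
  sum(as.integer(al) > 0L)
}

# Structural pre-scan so malformed input fails with a line number before
# the parser sees it.  Checks: header present, constant column count, GT
# declared in every FORMAT field.
validate_vcf_lines <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L) stop("VCF parse error: no #CHROM header line in ", path)
  ncol_hdr <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  if (ncol_hdr < 10L) {
    stop("VCF parse error at line ", hdr, ": no sample columns")
  }
  body <- seq.int(hdr + 1L, length.out = length(lines) - hdr)
  for (i in body) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != ncol_hdr) {
      stop("VCF parse error at line ", i, ": expected ", ncol_hdr,
           " fields, found ", length(f))
    }
    if (!("GT" %in% strsplit(f[9], ":", fixed = TRUE)[[1]])) {
      stop("VCF error at line ", i, ": GT absent from FORMAT")
    }
  }
  invisible(TRUE)
}

#' Write a genotype matrix to a VCF file
#'
#' Emits plain-text VCF v4.2 with per-sample GT and DP.  Missing calls are
#' written as \code{./.}, unknown depths as \code{.}.  The file round-trips:
#' \code{read_vcf(write_vcf(gm))} reproduces calls, depths, sample order
#' and variant order exactly.
#'
#' @param gm a non-empty \code{\link{genotype_matrix}}
#' @param path output path
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_samples(gm) == 0L || n_variants(gm) == 0L) {
    stop("refusing to write an empty genotype matrix")
  }
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$calls + 1L],
                   nrow = n_samples(gm))
  gt_str[is.na(gm$calls)] <- "./."
  dp_str <- ifelse(is.na(gm$depths), ".", as.character(gm$depths))
  body <- vapply(seq_len(n_variants(gm)), function(j) {
    v <- gm$variants[j, ]
    paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".", ".", "GT:DP",
            paste(gt_str[, j], dp_str[, j], sep = ":")),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ibspanel",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Merge genotype matrices onto a marker panel
#'
#' Stacks the samples of several genotype matrices and restricts the
#' variants to exactly those of a marker panel, in panel order.  Panel
#' variants are matched by (chrom, pos, ref, alt); a sample whose source
#' matrix lacks a panel variant is missing there.  This is how survey
#' samples genotyped on a reduced marker set are combined with reference
#' cultivars and outgroup samples before joint clustering.
#'
#' @param gm_list list of \code{\link{genotype_matrix}} objects with
#'   disjoint sample ids
#' @param panel a \code{\link{marker_panel}}, or any data frame with
#'   columns \code{chrom}, \code{pos}, \code{ref}, \code{alt} (and
#'   optionally \code{id})
#' @return a \code{\link{genotype_matrix}} with the union of samples and
#'   the panel's variants.
#' @export
merge_on_panel <- function(gm_list, panel) {
  if (inherits(panel, "marker_panel")) panel <- panel$variants
  panel <- as.data.frame(panel, stringsAsFactors = FALSE)
  if (nrow(panel) == 0L) stop("empty panel")
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(panel)))
  if (inherits(gm_list, "genotype_matrix")) gm_list <- list(gm_list)
  all_samples <- unlist(lapply(gm_list, `[[`, "samples"))
  if (anyDuplicated(all_samples)) {
    stop("duplicate sample ids across inputs: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  }
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
  pk <- key(panel)
  if (anyDuplicated(pk)) stop("duplicate variants in panel")
  n <- length(all_samples)
  m <- nrow(panel)
  calls <- matrix(NA_integer_, n, m)
  depths <- matrix(NA_integer_, n, m)
  row0 <- 0L
  for (gm in gm_list) {
    hit <- match(key(gm$variants), pk)
    src <- which(!is.na(hit))
    rows <- row0 + seq_len(n_samples(gm))
    calls[rows, hit[src]] <- gm$calls[, src]
    depths[rows, hit[src]] <- gm$depths[, src]
    row0 <- row0 + n_samples(gm)
  }
  variants <- data.frame(
    chrom = panel$chrom, pos = as.integer(panel$pos),
    id = if ("id" %in% names(panel)) panel$id
         else paste0(panel$chrom, ":", panel$pos),
    ref = panel$ref, alt = panel$alt, stringsAsFactors = FALSE
  )
  genotype_matrix(calls, depths, variants, samples = all_samples)
}
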