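#' Construct a genotype matrix
#'
#' The central container of the package: a samples x variants matrix of
#' diploid genotype dosages (count of alternate alleles, \code{0}, \code{1}
#' or \code{2}; \code{NA} for missing) together with per-call read depths
#' and a variant table.  Dosage \code{1} at a multi-allelic site means "one
#' non-reference allele"; such sites are flagged \code{biallelic = FALSE}
#' and are dropped by the quality-control cascade before any statistic that
#' assumes two alleles.
#'
#' @param calls integer matrix, samples in rows, variants in columns;
#'   entries in \code{c(0, 1, 2, NA)}.
#' @param depths integer matrix of the same dimension; non-negative read
#'   depths, \code{NA} where depth is unknown.  Defaults to all-unknown.
#' @param variants data frame with one row per column of \code{calls} and
#'   columns \code{chrom}, \code{pos} (1-based), \code{id}, \code{ref},
#'   \code{alt} (comma-separated if multi-allelic).  A logical
#'   \code{biallelic} column is derived from \code{alt} if absent.
#' @param samples character vector of unique sample ids; defaults to
#'   \code{rownames(calls)}.
#'
#' @return An object of class \code{"genotype_matrix"}: a list with
#'   elements \code{calls}, \code{depths}, \code{variants}, \code{samples}.
#' @export
genotype_matrix <- function(calls, depths = NULL, variants = NULL,
                            samples = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) {
    samples <- paste0("S", seq_len(nrow(calls)))
  }
  samples <- as.character(samples)
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (length(samples) != nrow(calls)) {
    stop("length(samples) != nrow(calls)")
  }
  if (is.null(depths)) {
    depths <- matrix(NA_integer_, nrow(calls), ncol(calls))
  }
  depths <- as.matrix(depths)
  storage.mode(depths) <- "integer"
  if (!identical(dim(depths), dim(calls))) {
    stop("calls and depths must have identical dimensions")
  }
  if (any(depths < 0L, na.rm = TRUE)) stop("negative depth")
  if (is.null(variants)) {
    variants <- data.frame(
      chrom = "chr1",
      pos = seq_len(ncol(calls)),
      id = if (is.null(colnames(calls))) paste0("v", seq_len(ncol(calls)))
           else colnames(calls),
      ref = "A", alt = "C",
      stringsAsFactors = FALSE
    )
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("variants must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(variants) != ncol(calls)) {
    stop("nrow(variants) != ncol(calls)")
  }
  if (any(variants$pos < 1L)) stop("variant pos must be >= 1 (1-based)")
  if (!"biallelic" %in% names(variants)) {
    variants$biallelic <- !grepl(",", variants$alt, fixed = TRUE)
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("calls must be 0, 1, 2 or NA")
  }
  dimnames(calls) <- list(samples, variants$id)
  dimnames(depths) <- list(samples, variants$id)
  structure(
    list(calls = calls, depths = depths, variants = variants,
         samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nb <- sum(x$variants$biallelic)
  miss <- mean(is.na(x$calls))
  cat(sprintf(
    "genotype_matrix: %d samples x %d variants (%d biallelic), %.1f%% missing calls\n",
    n_samples(x), n_variants(x), nb, 100 * miss))
  invisible(x)
}

#' Number of samples / variants in a genotype matrix
#' @param gm a \code{genotype_matrix}
#' @return integer count
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_samples
#' @export
n_variants <- function(gm) nrow(gm$variants)

#' Subset a genotype matrix
#'
#' Rows select samples, columns select variants; either index may be
#' logical, integer or (for samples) character.  Dimensions are always
#' kept, so the result is again a \code{genotype_matrix}.
#'
#' @param x a \code{genotype_matrix}
#' @param i sample index
#' @param j variant index
#' @param ... ignored
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$variants))
  if (is.character(i)) i <- match(i, x$samples)
  genotype_matrix(
    calls = x$calls[i, j, drop = FALSE],
    depths = x$depths[i, j, drop = FALSE],
    variants = x$variants[j, , drop = FALSE],
    samples = x$samples[i]
  )
}

#' @export
dim.genotype_matrix <- function(x) c(n_samples(x), n_variants(x))

#' Read a sample metadata table
#'
#' Tab-separated with header columns \code{sample_id}, \code{set_label}
#' (one of \code{cultivar}, \code{outgroup}, \code{survey}),
#' \code{subpop_label} (optional: \code{Eastern}, \code{Western},
#' \code{unknown} or empty) and optional \code{latitude}, \code{longitude}
#' in decimal degrees.
#'
#' @param path path to the TSV file
#' @return data frame with those columns; empty strings become \code{NA}.
#' @export
read_sample_info <- function(path) {
  info <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  if (!all(c("sample_id", "set_label") %in% names(info))) {
    stop("sample metadata needs columns sample_id and set_label")
  }
  if (anyDuplicated(info$sample_id)) stop("duplicate sample_id in metadata")
  ok_set <- c("cultivar", "outgroup", "survey")
  if (!all(info$set_label %in% ok_set)) {
    stop("set_label must be one of ", paste(ok_set, collapse = ", "))
  }
  if (!"subpop_label" %in% names(info)) info$subpop_label <- NA_character_
  bad <- !is.na(info$subpop_label) & info$set_label == "outgroup" &
    info$subpop_label %in% c("Eastern", "Western")
  if (any(bad)) {
    stop("outgroup samples must not carry Eastern/Western labels: ",
         paste(info$sample_id[bad], collapse = ", "))
  }
  info
}
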