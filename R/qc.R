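#' Mask low-coverage genotype calls
#'
#' Heterozygous calls cannot be made reliably at low read depth, so the
#' protocol marks genotypes sequenced below a depth threshold as missing
#' (default 10x).  Idempotent: masking twice equals masking once.
#'
#' @param gm a \code{\link{genotype_matrix}}
#' @param min_depth calls with depth strictly below this are set missing
#' @param unknown_depth policy for calls with no recorded depth:
#'   \code{"strict"} masks them (coverage unverifiable), \code{"lenient"}
#'   keeps them
#' @return the masked \code{genotype_matrix}; depths are unchanged.
#' @export
mask_low_depth <- function(gm, min_depth = 10L,
                           unknown_depth = c("strict", "lenient")) {
  unknown_depth <- match.arg(unknown_depth)
  stopifnot(inherits(gm, "genotype_matrix"), min_depth >= 0)
  if (min_depth == 0) return(gm)
  low <- !is.na(gm$depths) & gm$depths < min_depth
  if (unknown_depth == "strict") low <- low | is.na(gm$depths)
  gm$calls[low] <- NA_integer_
  gm
}

#' Missingness fractions
#'
#' Fraction of missing calls per variant (across samples) or per sample
#' (across variants), in [0, 1].
#'
#' @param gm a \code{\link{genotype_matrix}} with at least one sample and
#'   one variant
#' @return named numeric vector of fractions.
#' @export
variant_missingness <- function(gm) {
  stopifnot(n_samples(gm) >= 1L)
  colMeans(is.na(gm$calls))
}

#' @rdname variant_missingness
#' @export
sample_missingness <- function(gm) {
  stopifnot(n_variants(gm) >= 1L)
  rowMeans(is.na(gm$calls))
}

#' Staged genotype quality-control cascade
#'
#' Runs the four-stage filter that turns raw SNP calls into the
#' analysis-ready set, with the stages and boundary semantics of the study
#' protocol, in this fixed order:
#' \enumerate{
#'   \item mask genotypes with depth < \code{min_depth} as missing;
#'   \item drop variants with missingness > \code{variant_miss_max_stage1};
#'   \item drop samples with overall missingness > \code{sample_miss_max};
#'   \item recompute missingness on the surviving samples and retain only
#'     biallelic SNPs with missingness < \code{variant_miss_max_stage2}
#'     and Hardy-Weinberg exact test p-value > \code{hwe_p_min}.
#' }
#' Inequalities are strict exactly as written: a variant at missingness
#' 0.4 survives stage 2, but one at 0.1 is dropped at stage 4.
#' Monomorphic variants are not removed (no MAF filter); downstream PIC
#' ranking deprioritises them naturally.  Re-running the cascade on its
#' own output changes nothing.
#'
#' @param gm a \code{\link{genotype_matrix}}
#' @param min_depth stage-1 depth threshold (default 10)
#' @param variant_miss_max_stage1 stage-2 missingness bound (default 0.4)
#' @param sample_miss_max stage-3 missingness bound (default 0.3)
#' @param variant_miss_max_stage2 stage-4 missingness bound (default 0.1)
#' @param hwe_p_min stage-4 Hardy-Weinberg p-value floor (default 1e-6)
#' @param unknown_depth passed to \code{\link{mask_low_depth}}
#' @return a list with elements \code{gm} (the filtered matrix) and
#'   \code{report} (a \code{qc_report} of per-stage counts).
#' @export
run_qc_cascade <- function(gm, min_depth = 10L,
                           variant_miss_max_stage1 = 0.4,
                           sample_miss_max = 0.3,
                           variant_miss_max_stage2 = 0.1,
                           hwe_p_min = 1e-6,
                           unknown_depth = "strict") {
  stopifnot(inherits(gm, "genotype_matrix"))
  stages <- list()
  note <- function(name, threshold, before, after) {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = name, threshold = threshold,
      samples_in = dim(before)[1], samples_out = dim(after)[1],
      variants_in = dim(before)[2], variants_out = dim(after)[2],
      stringsAsFactors = FALSE)
    if (dim(after)[1] == 0L || dim(after)[2] == 0L) {
      stop("all data filtered out at stage '", name, "'")
    }
  }

  g1 <- mask_low_depth(gm, min_depth, unknown_depth)
  note("depth_mask", min_depth, gm, g1)

  keep_v <- variant_missingness(g1) <= variant_miss_max_stage1
  g2 <- g1[, keep_v]
  note("variant_missingness", variant_miss_max_stage1, g1, g2)

  keep_s <- sample_missingness(g2) <= sample_miss_max
  g3 <- g2[keep_s, ]
  note("sample_missingness", sample_miss_max, g2, g3)

  vm <- variant_missingness(g3)            # recomputed on surviving samples
  keep_v2 <- g3$variants$biallelic & vm < variant_miss_max_stage2
  hwe_p <- rep(NA_real_, n_variants(g3))
  idx <- which(keep_v2)
  for (j in idx) {
    cnt <- genotype_counts(g3$calls[, j])
    hwe_p[j] <- if (sum(cnt) == 0L) 1 else hwe_exact_p(cnt)
  }
  keep_v2[idx] <- hwe_p[idx] > hwe_p_min
  g4 <- g3[, keep_v2]
  note("biallelic_missingness_hwe",
       paste0("miss<", variant_miss_max_stage2, ", p>", hwe_p_min), g3, g4)

  report <- structure(do.call(rbind, stages), class = c("qc_report", "data.frame"))
  list(gm = g4, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC cascade:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-28s (%s): samples %d -> %d, variants %d -> %d\n",
                x$stage[i], x$threshold[i],
                x$samples_in[i], x$samples_out[i],
                x$variants_in[i], x$variants_out[i]))
  }
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report a \code{qc_report} from \code{\link{run_qc_cascade}}
#' @param path output path
#' @return \code{path}, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
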