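#' Greedy windowed linkage-disequilibrium pruning
#'
#' Thins a marker set to an approximately independent subset: within each
#' sliding window of \code{window} variants, whenever a retained pair has
#' squared genotype correlation at or above \code{r2_max}, the
#' later-positioned variant of the pair is removed (keep-first rule); the
#' window then slides by \code{step} variants.  Windows never span
#' chromosomes.  Pairs whose r-squared is undefined (zero variance or
#' fewer than two shared complete calls) are never pruned on that basis.
#' \code{window = Inf} performs global all-pairs pruning, useful for small
#' sets.
#'
#' @param gm a \code{\link{genotype_matrix}} with variants sorted by
#'   (chrom, pos); unsorted input is an error
#' @param r2_max prune threshold on squared correlation (default 0.1, so
#'   the retained set has all pairwise LD below 0.1)
#' @param window window size in number of variants (default 50)
#' @param step slide in number of variants (default 5)
#' @return integer vector of retained variant indices, in genomic order.
#' @export
ld_prune <- function(gm, r2_max = 0.1, window = 50L, step = 5L) {
  stopifnot(inherits(gm, "genotype_matrix"), r2_max > 0, step >= 1L)
  v <- gm$variants
  o <- order(v$chrom, v$pos)
  if (!identical(o, seq_len(nrow(v)))) {
    stop("variants must be sorted by (chrom, pos) before LD pruning")
  }
  keep <- rep(TRUE, nrow(v))
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    w <- if (is.finite(window)) as.integer(window) else length(idx)
    starts <- if (length(idx) <= w) 1L else
      unique(c(seq(1L, length(idx) - w + 1L, by = step),
               length(idx) - w + 1L))
    for (s in starts) {
      win <- idx[s:min(s + w - 1L, length(idx))]
      act <- win[keep[win]]
      if (length(act) < 2L) next
      r2 <- suppressWarnings(
        stats::cor(gm$calls[, act, drop = FALSE],
                   use = "pairwise.complete.obs")^2)
      # pairwise n >= 2 guard: cor() happily returns +/-1 from 2 points,
      # which is fine, but with < 2 complete pairs it yields NA already.
      nloc <- length(act)
      alive <- rep(TRUE, nloc)
      for (i in seq_len(nloc - 1L)) {
        if (!alive[i]) next
        for (j in seq.int(i + 1L, nloc)) {
          if (!alive[j]) next
          rij <- r2[i, j]
          if (!is.na(rij) && rij >= r2_max) alive[j] <- FALSE
        }
      }
      keep[act[!alive]] <- FALSE
    }
  }
  which(keep)
}

#' Select a highly informative marker panel
#'
#' From an LD-pruned variant set, retains the biallelic variants whose
#' polymorphism information content is at least \code{pic_min}
#' (inclusive), ordered by genomic position.  The default 0.37 sits just
#' under the biallelic maximum of 0.375, so the panel keeps only markers
#' with near-balanced allele frequencies — the most informative ones for
#' telling cultivars apart.
#'
#' @param gm the \code{\link{genotype_matrix}} the pruning ran on
#' @param pruned integer indices from \code{\link{ld_prune}} (or any
#'   variant subset)
#' @param pic_min PIC threshold, inclusive (default 0.37)
#' @param provenance optional named list of upstream parameters (e.g.
#'   r2_max, window, step, seed) recorded alongside the thresholds
#' @return object of class \code{"marker_panel"}: list with
#'   \code{variants} (data frame chrom, pos, id, ref, alt, maf, pic) and
#'   \code{provenance}.  Empty selection yields an empty panel with a
#'   warning.
#' @export
select_panel <- function(gm, pruned = seq_len(n_variants(gm)),
                         pic_min = 0.37, provenance = list()) {
  stopifnot(inherits(gm, "genotype_matrix"),
            all(pruned >= 1L), all(pruned <= n_variants(gm)))
  pruned <- sort(unique(as.integer(pruned)))
  scores <- rep(NA_real_, length(pruned))
  mafs <- rep(NA_real_, length(pruned))
  for (k in seq_along(pruned)) {
    j <- pruned[k]
    if (!gm$variants$biallelic[j]) next
    cnt <- genotype_counts(gm$calls[, j])
    if (sum(cnt) == 0L) next
    mafs[k] <- maf(cnt)
    scores[k] <- pic(mafs[k])
  }
  sel <- which(!is.na(scores) & scores >= pic_min)
  if (length(sel) == 0L) warning("no variants reach PIC >= ", pic_min,
                                 "; returning an empty panel")
  j <- pruned[sel]
  vars <- gm$variants[j, c("chrom", "pos", "id", "ref", "alt"), drop = FALSE]
  vars$maf <- mafs[sel]
  vars$pic <- scores[sel]
  o <- order(vars$chrom, vars$pos)
  vars <- vars[o, , drop = FALSE]
  rownames(vars) <- NULL
  structure(
    list(variants = vars,
         provenance = c(list(pic_min = pic_min,
                             n_candidates = length(pruned)), provenance)),
    class = "marker_panel"
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d variants (PIC >= %s)",
              nrow(x$variants), format(x$provenance$pic_min)))
  if (nrow(x$variants)) {
    cat(sprintf(", PIC range [%.4f, %.4f]",
                min(x$variants$pic), max(x$variants$pic)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.marker_panel <- function(x) nrow(x$variants)

#' Write a marker panel and its provenance
#'
#' Panel as TSV (chrom, pos, id, ref, alt, maf, pic); thresholds and
#' pruning parameters as a JSON sidecar next to it.
#'
#' @param panel a \code{marker_panel}
#' @param path output TSV path; the sidecar is \code{<path>.provenance.json}
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel$variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(panel$provenance, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Correlation between two distance matrices
#'
#' Pearson correlation over the strictly-lower-triangle entries of two
#' distance matrices on the same samples in the same order — the fidelity
#' measure for how well a reduced marker panel reproduces the full-set
#' distances.
#'
#' @param dm_full,dm_panel \code{ibs_dist} objects (or symmetric matrices)
#'   with identical sample sets and ordering
#' @return Pearson r in [-1, 1].
#' @export
matrix_correlation <- function(dm_full, dm_panel) {
  a <- if (inherits(dm_full, "ibs_dist")) dm_full$d else as.matrix(dm_full)
  b <- if (inherits(dm_panel, "ibs_dist")) dm_panel$d else as.matrix(dm_panel)
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b))) {
    stop("distance matrices must share the same samples in the same order")
  }
  x <- a[lower.tri(a)]
  y <- b[lower.tri(b)]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined statistic: zero variance in a distance triangle")
  }
  stats::cor(x, y)
}

#' Mantel permutation test between two distance matrices
#'
#' The observed statistic is \code{\link{matrix_correlation}}; the null
#' distribution is built by simultaneously permuting the rows and columns
#' of the second matrix.  The one-sided p-value is
#' \eqn{(1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})}, so it is never
#' exactly zero.  Deterministic given \code{seed}; the caller's RNG state
#' is left untouched.
#'
#' @param dm_a,dm_b distance matrices on the same samples, same order
#' @param n_perm number of permutations (default 999)
#' @param seed integer seed, required for reproducibility
#' @return list with \code{mantel_r}, \code{mantel_p}, \code{n_perm}.
#' @export
mantel_test <- function(dm_a, dm_b, n_perm = 999L, seed) {
  stopifnot(n_perm >= 1L)
  if (missing(seed)) stop("mantel_test requires an explicit seed")
  a <- if (inherits(dm_a, "ibs_dist")) dm_a$d else as.matrix(dm_a)
  b <- if (inherits(dm_b, "ibs_dist")) dm_b$d else as.matrix(dm_b)
  r_obs <- matrix_correlation(a, b)
  lt <- lower.tri(a)
  x <- a[lt]
  n <- nrow(a)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      stats::cor(x, b[p, p][lt])
    }, numeric(1))
  })
  list(mantel_r = r_obs,
       mantel_p = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
       n_perm = as.integer(n_perm))
}
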