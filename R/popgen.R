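#' Genotype counts at a biallelic variant
#'
#' Tallies non-missing diploid dosages into the triple (reference
#' homozygotes, heterozygotes, alternate homozygotes) that the
#' single-marker statistics consume.
#'
#' @param dosages integer vector of dosages in \code{c(0, 1, 2, NA)}
#' @return named integer vector \code{c(n_ref_hom, n_het, n_alt_hom)}.
#' @export
genotype_counts <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  c(n_ref_hom = sum(d == 0L), n_het = sum(d == 1L), n_alt_hom = sum(d == 2L))
}

#' Minor allele frequency
#'
#' @param counts genotype counts \code{c(n_ref_hom, n_het, n_alt_hom)}
#'   (order as returned by \code{\link{genotype_counts}})
#' @return the frequency of the rarer allele, in [0, 0.5].
#' @export
maf <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("undefined statistic: no non-missing genotypes")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  min(p, 1 - p)
}

#' Polymorphism information content of a biallelic marker
#'
#' For a biallelic SNP with minor allele frequency \eqn{a},
#' \deqn{PIC = 1 - (a^2 + (1-a)^2) - 2 a^2 (1-a)^2,}
#' the expected probability that a marker distinguishes a random pair of
#' individuals informative for linkage.  It is strictly increasing in
#' \eqn{a} on [0, 0.5] and attains its biallelic maximum 0.375 at
#' \eqn{a = 0.5}; monomorphic markers score 0.  Vectorised.
#'
#' @param a minor allele frequency (or vector thereof) in [0, 0.5]
#' @return PIC score(s) in [0, 0.375].
#' @export
pic <- function(a) {
  if (any(is.na(a)) || any(a < 0) || any(a > 0.5)) {
    stop("minor allele frequency must lie in [0, 0.5]")
  }
  1 - (a^2 + (1 - a)^2) - 2 * a^2 * (1 - a)^2
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test of Hardy-Weinberg genotype proportions: given
#' the observed allele counts, every heterozygote count with the same
#' parity is enumerated, and the p-value is the total probability of
#' configurations no more probable than the observed one (the standard
#' two-sided exact test, not the mid-p variant).  Probability ties are
#' included in the sum, compared with a 1e-12 relative tolerance to absorb
#' floating-point noise.
#'
#' @param counts genotype counts \code{c(n_ref_hom, n_het, n_alt_hom)}
#'   with at least one non-missing genotype
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(counts) {
  counts <- as.integer(round(as.numeric(counts)))
  stopifnot(length(counts) == 3L, all(counts >= 0L))
  n <- sum(counts)
  if (n == 0L) stop("undefined statistic: no non-missing genotypes")
  n_minor <- min(2L * counts[1] + counts[2], 2L * counts[3] + counts[2])
  n_major <- 2L * n - n_minor
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  # log P(n_het = h | n, n_minor) for the exact conditional distribution
  logp <- lfactorial(n) -
    lfactorial((n_minor - hets) / 2) - lfactorial(hets) -
    lfactorial((n_major - hets) / 2) +
    hets * log(2) + lfactorial(n_minor) + lfactorial(n_major) -
    lfactorial(2L * n)
  p <- exp(logp)
  p_obs <- p[match(counts[2], hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Squared genotype correlation between two markers
#'
#' Squared Pearson correlation of dosages over pairwise-complete samples
#' (the composite, phase-free linkage-disequilibrium estimate appropriate
#' for unphased dosage data).  Returns \code{NA} when fewer than two
#' complete pairs exist or either marker has zero variance over the shared
#' samples; callers treat an undefined value as "not prunable".
#'
#' @param g1,g2 dosage vectors of equal length (entries 0, 1, 2 or NA)
#' @return r-squared in [0, 1], or \code{NA}.
#' @export
genotype_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2L) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Per-variant summary statistics
#'
#' Sample size, minor allele frequency, PIC and Hardy-Weinberg exact
#' p-value for every biallelic variant (non-biallelic variants get NA
#' statistics).  Computed over non-missing calls only.
#'
#' @param gm a \code{\link{genotype_matrix}}
#' @return data frame with columns \code{id}, \code{chrom}, \code{pos},
#'   \code{n}, \code{maf}, \code{pic}, \code{hwe_p}, one row per variant,
#'   suitable for \code{write.table}.
#' @export
variant_stats <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- n_variants(gm)
  out <- data.frame(
    id = gm$variants$id, chrom = gm$variants$chrom, pos = gm$variants$pos,
    n = NA_integer_, maf = NA_real_, pic = NA_real_, hwe_p = NA_real_,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(m)) {
    cnt <- genotype_counts(gm$calls[, j])
    nj <- sum(cnt)
    out$n[j] <- nj
    if (gm$variants$biallelic[j] && nj > 0L) {
      out$maf[j] <- maf(cnt)
      out$pic[j] <- pic(out$maf[j])
      out$hwe_p[j] <- hwe_exact_p(cnt)
    }
  }
  out
}
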