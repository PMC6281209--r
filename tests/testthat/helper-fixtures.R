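# Quick constructors used across test files.

gm_from_calls <- function(calls, depths = NULL, chrom = "chr1",
                          pos = NULL, alt = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  variants <- data.frame(
    chrom = chrom,
    pos = if (is.null(pos)) 100L * seq_len(m) else pos,
    id = paste0("v", seq_len(m)),
    ref = "A",
    alt = if (is.null(alt)) rep("C", m) else alt,
    stringsAsFactors = FALSE
  )
  genotype_matrix(calls, depths, variants,
                  samples = paste0("S", seq_len(nrow(calls))))
}

random_gm <- function(n, m, miss = 0.1) {
  calls <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  calls[runif(n * m) < miss] <- NA_integer_
  gm_from_calls(calls)
}

# A random symmetric dissimilarity matrix with zero diagonal.
random_dist <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 1)
  d <- d + t(d)
  dimnames(d) <- list(paste0("S", 1:n), paste0("S", 1:n))
  d
}
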