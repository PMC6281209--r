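# Independent brute-force oracles.  Each one takes a different route than
# the package implementation so agreement is meaningful.

# Exact HWE p-value by direct enumeration with the closed-form factorial
# expression for each heterozygote count (safe up to 2n = 170).
oracle_hwe <- function(n_ref_hom, n_het, n_alt_hom) {
  n <- n_ref_hom + n_het + n_alt_hom
  na <- 2 * n_ref_hom + n_het
  nb <- 2 * n_alt_hom + n_het
  hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  prob <- sapply(hets, function(h) {
    a <- (na - h) / 2
    b <- (nb - h) / 2
    factorial(n) / (factorial(a) * factorial(h) * factorial(b)) *
      2^h * factorial(na) * factorial(nb) / factorial(2 * n)
  })
  p_obs <- prob[hets == n_het]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

# (1 - IBS) by explicit allele multisets: dosage -> allele pair, sharing =
# size of the multiset intersection / 2, averaged over complete loci.
oracle_ibs <- function(calls) {
  alleles <- list(`0` = c("R", "R"), `1` = c("R", "A"), `2` = c("A", "A"))
  share1 <- function(a, b) {
    pa <- alleles[[as.character(a)]]
    pb <- alleles[[as.character(b)]]
    inter <- sum(pmin(table(factor(pa, c("R", "A"))),
                      table(factor(pb, c("R", "A")))))
    inter / 2
  }
  n <- nrow(calls)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- which(!is.na(calls[i, ]) & !is.na(calls[j, ]))
    s <- mean(sapply(ok, function(l) share1(calls[i, l], calls[j, l])))
    d[i, j] <- d[j, i] <- 1 - s
  }
  dimnames(d) <- list(rownames(calls), rownames(calls))
  d
}

# Literal agglomerative ward.D: scan for the global minimum entry, merge,
# update every other distance with the Lance-Williams ward-1 coefficients.
# Returns merge heights and the cophenetic matrix.
oracle_ward <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  heights <- numeric(n - 1)
  coph <- matrix(0, n, n)
  for (step in seq_len(n - 1)) {
    m <- length(active)
    best <- c(NA, NA)
    bestd <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (d[i, j] < bestd) { bestd <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- bestd
    coph[active[[i]], active[[j]]] <- bestd
    coph[active[[j]], active[[i]]] <- bestd
    ni <- sizes[i]; nj <- sizes[j]
    newd <- sapply(seq_len(m), function(k) {
      if (k == i || k == j) return(NA_real_)
      nk <- sizes[k]
      ((ni + nk) * d[k, i] + (nj + nk) * d[k, j] - nk * d[i, j]) /
        (ni + nj + nk)
    })
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    sizes <- c(sizes[keep], ni + nj)
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
  }
  list(heights = heights, cophenetic = coph)
}

# Literal "remove the later variant of the first offending pair, repeat"
# all-pairs LD pruning at small n.
oracle_ld_prune <- function(gm, r2_max) {
  kept <- seq_len(n_variants(gm))
  repeat {
    offender <- NULL
    for (a in seq_along(kept)) {
      for (b in seq_along(kept)) {
        if (b <= a) next
        r2 <- genotype_r2(gm$calls[, kept[a]], gm$calls[, kept[b]])
        if (!is.na(r2) && r2 >= r2_max) { offender <- b; break }
      }
      if (!is.null(offender)) break
    }
    if (is.null(offender)) break
    kept <- kept[-offender]
  }
  kept
}
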