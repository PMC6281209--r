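test_that("(1-IBS) distances follow the allele-sharing convention", {
  gm <- gm_from_calls(rbind(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(unname(ibs_distance(gm)$d[1, 2]), 0)
  gm2 <- gm_from_calls(rbind(c(0, 0, 0), c(2, 2, 2)))
  expect_equal(unname(ibs_distance(gm2)$d[1, 2]), 1)
  gm3 <- gm_from_calls(rbind(c(0, 1, 2), c(2, 1, 0)))
  expect_equal(unname(ibs_distance(gm3)$d[1, 2]), 2 / 3)
  # heterozygote vs heterozygote is full sharing
  gm4 <- gm_from_calls(rbind(c(1, 1), c(1, 1)))
  expect_equal(unname(ibs_distance(gm4)$d[1, 2]), 0)
})

test_that("(1-IBS) matches the per-allele sharing oracle on random matrices with missingness", {
  set.seed(31)
  for (k in 1:20) {
    gm <- random_gm(5, 20, miss = 0.15)
    d <- ibs_distance(gm)
    expect_equal(d$d, oracle_ibs(gm$calls), tolerance = 1e-12)
    expect_true(all(d$d >= 0 & d$d <= 1))
    expect_equal(unname(diag(d$d)), rep(0, 5))
    expect_identical(d$d, t(d$d))
  }
})

test_that("overlap is tracked per pair and a zero-overlap pair is an error", {
  calls <- rbind(c(0L, NA, 1L), c(2L, 1L, NA), c(NA, 0L, 2L))
  gm <- gm_from_calls(calls)
  d <- ibs_distance(gm)
  expect_equal(unname(d$overlap[1, 2]), 1)
  disjoint <- gm_from_calls(rbind(c(0L, NA), c(NA, 2L)))
  expect_error(ibs_distance(disjoint), "S1 / S2")
})

test_that("ward.D reproduces the hand-worked merge heights", {
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- ward_cluster(d2)
  expect_equal(t2$hclust$height, 1)
  d3 <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- ward_cluster(d3)
  # first merge (A,B) at 1; then ((1+1)*4 + (1+1)*4 - 1*1)/3 = 5
  expect_equal(t3$hclust$height, c(1, 5))
  expect_equal(sort(stats::cutree(t3$hclust, 2)[c("A", "B")]),
               c(A = 1, B = 1))
})

test_that("ward.D agrees with the brute-force Lance-Williams oracle on random matrices", {
  set.seed(17)
  for (k in 1:15) {
    n <- sample(4:8, 1)
    d <- random_dist(n)
    tr <- ward_cluster(d)
    orc <- oracle_ward(d)
    expect_equal(tr$hclust$height, orc$heights, tolerance = 1e-10)
    expect_equal(as.matrix(stats::cophenetic(tr$hclust)), orc$cophenetic,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("ward_cluster validates its input", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(ward_cluster(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(ward_cluster(neg), "negative")
})

test_that("clonal duplicates merge first at height zero", {
  set.seed(12)
  cfg <- sim_config(n_east = 8, n_west = 8, n_outgroup = 0, n_clones = 4,
                    n_progeny = 0, n_markers = 400, missing_rate = 0,
                    depth_mean = 60, seed = 12)
  sim <- simulate_genotypes(cfg)
  d <- ibs_distance(sim$gm)
  tr <- ward_cluster(d)
  clones <- sim$truth[sim$truth$role == "clone", ]
  h <- tr$hclust$height
  for (i in seq_len(nrow(clones))) {
    pair <- c(clones$sample_id[i], clones$clone_parent[i])
    expect_equal(unname(d$d[pair[1], pair[2]]), 0)
  }
  # at least one zero-height merge per distinct clone pair
  expect_gte(sum(h < 1e-12), length(unique(clones$clone_parent)))
})

test_that("newick export preserves topology and heights through a parse round trip", {
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  nw <- to_newick(ward_cluster(d2))
  expect_match(gsub("\\s", "", nw), "^\\((A:1,B:1|B:1,A:1)\\);$")

  set.seed(23)
  gm <- random_gm(7, 60, miss = 0.05)
  tr <- ward_cluster(ibs_distance(gm))
  back <- ape::read.tree(text = to_newick(tr))
  expect_equal(sort(back$tip.label), sort(tr$phylo$tip.label))
  # same pairwise path heights: compare ultrametric tip-to-tip distances
  cd <- ape::cophenetic.phylo(back)
  hd <- 2 * as.matrix(stats::cophenetic(tr$hclust))  # path = 2 x merge height
  expect_equal(cd[rownames(hd), colnames(hd)], hd, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("labels with spaces are escaped for newick", {
  calls <- rbind(c(0, 1), c(2, 1), c(0, 0))
  gm <- genotype_matrix(calls, samples = c("Ajwa medina", "Khir", "Lulu"))
  tr <- ward_cluster(ibs_distance(gm))
  back <- ape::read.tree(text = to_newick(tr))
  expect_true("Ajwa_medina" %in% back$tip.label)
})

test_that("outgroup orientation flags monophyly and never alters heights", {
  set.seed(19)
  cfg <- sim_config(n_east = 6, n_west = 6, n_outgroup = 4, n_clones = 0,
                    n_progeny = 0, n_markers = 500, seed = 19)
  sim <- simulate_genotypes(cfg)
  tr <- ward_cluster(ibs_distance(sim$gm))
  og <- sim$info$sample_id[sim$info$set_label == "outgroup"]
  tr2 <- orient_by_outgroup(tr, og)
  expect_true(tr2$outgroup_monophyletic)
  expect_identical(tr2$hclust$height, tr$hclust$height)
  expect_equal(sort(tr2$phylo$edge.length), sort(tr$phylo$edge.length))
  # outgroup drawn first: the first tips in cladewise order are the outgroup
  first_tips <- tr2$phylo$edge[, 2][tr2$phylo$edge[, 2] <= length(tr2$labels)]
  expect_setequal(tr2$phylo$tip.label[first_tips[seq_along(og)]], og)

  expect_error(orient_by_outgroup(tr, "nope"), "unknown outgroup")

  # scattered outgroup ids cannot be monophyletic
  scattered <- c(og[1], sim$info$sample_id[1])
  expect_warning(tr3 <- orient_by_outgroup(tr, scattered), "not monophyletic")
  expect_false(tr3$outgroup_monophyletic)

  single <- orient_by_outgroup(tr, og[1])
  expect_true(single$outgroup_monophyletic)
})

test_that("label propagation assigns by majority within the cut clusters", {
  # build a tree with three clean clusters from block distances
  d <- matrix(0.9, 12, 12)
  ids <- paste0("S", 1:12)
  dimnames(d) <- list(ids, ids)
  blocks <- list(1:4, 5:8, 9:12)
  for (b in blocks) d[b, b] <- 0.05
  diag(d) <- 0
  tr <- ward_cluster(d)
  labels <- c(S1 = "Eastern", S2 = "Eastern", S3 = "Eastern",
              S5 = "Eastern", S6 = "Eastern", S7 = "Western")
  res <- propagate_labels(tr, labels, k_top = 3)
  expect_equal(unname(res$labels["S4"]), "Eastern")     # unanimous cluster
  expect_equal(unname(res$labels["S8"]), "Eastern")     # 2:1 majority
  expect_equal(unname(res$labels["S9"]), "unknown")     # unlabeled cluster
  expect_equal(res$unresolved_clusters,
               unique(res$table$cluster[res$table$sample_id == "S9"]))
  # previously labeled samples keep their own labels
  expect_equal(unname(res$labels["S7"]), "Western")
  expect_equal(res$table$evidence_count[res$table$sample_id == "S4"], 3L)
  expect_equal(res$table$evidence_count[res$table$sample_id == "S8"], 2L)
})

test_that("a tied majority refuses to guess", {
  d <- matrix(0.9, 4, 4)
  ids <- paste0("S", 1:4)
  dimnames(d) <- list(ids, ids)
  d[1:3, 1:3] <- 0.05
  diag(d) <- 0
  tr <- ward_cluster(d)
  res <- propagate_labels(tr, c(S1 = "Eastern", S2 = "Western"), k_top = 2)
  expect_equal(unname(res$labels["S3"]), "unknown")
})
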