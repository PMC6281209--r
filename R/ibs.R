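#' Pairwise (1 - IBS) distance matrix
#'
#' Identity-by-state similarity between two samples is the mean, over loci
#' where both are called, of the fraction of alleles shared in state:
#' identical genotypes share 1, a homozygote and a heterozygote (or the
#' two opposite combinations differing by one dosage unit) share 0.5, and
#' opposite homozygotes share 0.  Equivalently the per-locus sharing is
#' \eqn{1 - |g_i - g_j|/2} on dosages.  The distance is 1 - IBS, in
#' [0, 1], computed over pairwise-complete loci (per-pair denominators, so
#' no data are wasted on a sample with scattered missingness).
#'
#' @param gm a \code{\link{genotype_matrix}} with at least two samples;
#'   every pair must share at least one non-missing locus
#' @return an object of class \code{"ibs_dist"}: list with \code{d}
#'   (symmetric distance matrix, zero diagonal), \code{overlap} (pairwise
#'   non-missing locus counts) and \code{samples}.
#' @export
ibs_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"), n_samples(gm) >= 2L)
  A <- gm$calls
  M <- !is.na(A)
  A[!M] <- 0L
  storage.mode(A) <- "double"
  storage.mode(M) <- "double"
  overlap <- M %*% t(M)
  # sum over complete loci of |gi - gj|, via
  # |d| = (d^2 + [exactly one of the pair is heterozygous]) / 2
  Q <- (A * A) %*% t(M)
  d2 <- Q + t(Q) - 2 * (A %*% t(A))
  H <- (A == 1) * M
  xor_het <- H %*% t(M - H) + (M - H) %*% t(H)
  if (any(overlap[upper.tri(overlap)] < 1)) {
    bad <- which(overlap < 1 & upper.tri(overlap), arr.ind = TRUE)[1, ]
    stop("no shared non-missing loci for pair ",
         gm$samples[bad[1]], " / ", gm$samples[bad[2]])
  }
  d <- (d2 + xor_het) / (4 * overlap)
  diag(d) <- 0
  d <- (d + t(d)) / 2                       # enforce exact symmetry
  dimnames(d) <- list(gm$samples, gm$samples)
  dimnames(overlap) <- dimnames(d)
  structure(list(d = d, overlap = overlap, samples = gm$samples),
            class = "ibs_dist")
}

#' @export
print.ibs_dist <- function(x, ...) {
  off <- x$d[lower.tri(x$d)]
  cat(sprintf("ibs_dist: %d samples; (1-IBS) range [%.4f, %.4f], mean %.4f\n",
              length(x$samples), min(off), max(off), mean(off)))
  invisible(x)
}

#' @export
as.matrix.ibs_dist <- function(x, ...) x$d

#' @export
as.dist.ibs_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' Distance matrix I/O
#'
#' Square TSV with sample ids as header row and first column, values at
#' full double precision.
#'
#' @param dm an \code{ibs_dist} (or bare symmetric matrix for writing)
#' @param path file path
#' @return \code{write_distance_tsv}: \code{path} invisibly;
#'   \code{read_distance_tsv}: an \code{ibs_dist} (overlap unknown,
#'   recorded as NA).
#' @export
write_distance_tsv <- function(dm, path) {
  d <- if (inherits(dm, "ibs_dist")) dm$d else as.matrix(dm)
  df <- data.frame(sample_id = rownames(d),
                   format(d, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  d <- as.matrix(df[, -1, drop = FALSE])
  dimnames(d) <- list(ids, ids)
  structure(list(d = d, overlap = array(NA_real_, dim(d)), samples = ids),
            class = "ibs_dist")
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with Ward's minimum-variance criterion applied
#' to the raw (unsquared) dissimilarities — the classic "ward.D"
#' convention, i.e. the Lance-Williams update
#' \deqn{d(k, i \cup j) = \frac{(n_i+n_k)d(k,i) + (n_j+n_k)d(k,j) - n_k d(i,j)}{n_i+n_j+n_k}.}
#' Merge heights are the criterion values at each agglomeration.  The
#' returned tree carries both the \code{hclust} object (for cuts) and a
#' \code{phylo} representation in which a leaf's branch length equals its
#' parent's merge height, so edge lengths sum to merge heights.
#'
#' @param dm an \code{\link{ibs_distance}} result, a \code{dist}, or a
#'   symmetric non-negative matrix with zero diagonal
#' @return an object of class \code{"cluster_tree"}: list with
#'   \code{hclust}, \code{phylo}, \code{labels}, and an
#'   \code{outgroup_monophyletic} flag (NA until oriented).
#' @export
ward_cluster <- function(dm) {
  d <- if (inherits(dm, "ibs_dist")) dm$d
       else if (inherits(dm, "dist")) as.matrix(dm)
       else as.matrix(dm)
  if (nrow(d) < 2L) stop("need at least two samples")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("negative dissimilarity")
  if (any(abs(diag(d)) > 1e-12)) stop("nonzero diagonal")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D")
  structure(
    list(hclust = hc, phylo = phylo_from_hclust(hc),
         labels = hc$labels, outgroup_monophyletic = NA),
    class = "cluster_tree"
  )
}

# Build an ape phylo from an hclust, with ultrametric edge lengths:
# edge length = parent merge height - child height (leaves at height 0).
phylo_from_hclust <- function(hc) {
  n <- length(hc$order)
  if (is.null(hc$labels)) hc$labels <- paste0("S", seq_len(n))
  if (n == 2L) {
    edge <- matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE)
    phy <- list(edge = edge, edge.length = rep(hc$height[1], 2),
                tip.label = sanitize_labels(hc$labels), Nnode = 1L)
    class(phy) <- "phylo"
    return(phy)
  }
  node_of_merge <- n + (n - seq_len(n - 1L))   # merge row n-1 -> root n+1
  edges <- matrix(0L, 2L * (n - 1L), 2L)
  lens <- numeric(2L * (n - 1L))
  r <- 0L
  for (i in seq_len(n - 1L)) {
    for (child in hc$merge[i, ]) {
      r <- r + 1L
      edges[r, 1L] <- node_of_merge[i]
      if (child < 0L) {
        edges[r, 2L] <- -child
        lens[r] <- hc$height[i]
      } else {
        edges[r, 2L] <- node_of_merge[child]
        lens[r] <- hc$height[i] - hc$height[child]
      }
    }
  }
  phy <- list(edge = edges, edge.length = lens,
              tip.label = sanitize_labels(hc$labels), Nnode = n - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

# Newick cannot hold raw spaces; underscore-escape (standard convention).
sanitize_labels <- function(x) gsub("[[:space:]]+", "_", x)

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: %d leaves, ward.D merge heights [%.4g, %.4g]",
              length(x$labels), min(x$hclust$height), max(x$hclust$height)))
  if (!is.na(x$outgroup_monophyletic)) {
    cat(sprintf("; outgroup %s", if (x$outgroup_monophyletic)
      "monophyletic" else "NOT monophyletic"))
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.cluster_tree <- function(x, ...) {
  ape::plot.phylo(x$phylo, ...)
}

#' Orient a cluster tree by its outgroup
#'
#' Rotates internal nodes so the smallest clade containing every outgroup
#' sample is drawn first at its level — the conventional rooted
#' presentation with the outgroup on top.  Merge structure and heights are
#' untouched (rotation only reorders children).  If that clade also
#' contains non-outgroup leaves the tree is flagged
#' \code{outgroup_monophyletic = FALSE} with a warning, since rooting
#' between outgroup and ingroup is then not clean.
#'
#' @param tree a \code{\link{ward_cluster}} result
#' @param outgroup_ids character vector of leaf labels, non-empty, all
#'   present in the tree
#' @return the re-oriented \code{cluster_tree}, with
#'   \code{outgroup_monophyletic} set and the outgroup ids stored.
#' @export
orient_by_outgroup <- function(tree, outgroup_ids) {
  stopifnot(inherits(tree, "cluster_tree"), length(outgroup_ids) >= 1L)
  tips <- sanitize_labels(as.character(outgroup_ids))
  phy <- tree$phylo
  unknown <- setdiff(tips, phy$tip.label)
  if (length(unknown)) {
    stop("unknown outgroup id(s): ", paste(unknown, collapse = ", "))
  }
  n <- length(phy$tip.label)
  root <- n + 1L
  mrca <- if (length(tips) == 1L) match(tips, phy$tip.label)
          else ape::getMRCA(phy, tips)
  mono <- length(tips) == 1L ||
    setequal(ape::extract.clade(phy, mrca)$tip.label, tips)
  if (!mono) warning("outgroup is not monophyletic")
  if (mrca != root) {
    path <- ape::nodepath(phy, root, mrca)
    for (i in seq_len(length(path) - 1L)) {
      node <- path[i]
      kids <- phy$edge[phy$edge[, 1] == node, 2]
      if (kids[1] != path[i + 1L]) {
        phy <- ape::rotate(phy, node)
        phy <- ape::reorder.phylo(phy, "cladewise")
      }
    }
  }
  tree$phylo <- phy
  tree$outgroup_monophyletic <- mono
  tree$outgroup_ids <- as.character(outgroup_ids)
  tree
}

#' Export a cluster tree as a Newick string
#'
#' Branch lengths derive from merge heights (parent height minus child
#' height; leaves sit at height 0), so the string preserves the dendrogram
#' exactly and parses back to an identical topology and heights.  Written
#' files load in standard tree viewers.
#'
#' @param tree a \code{cluster_tree}
#' @return single Newick string, semicolon-terminated.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  ape::write.tree(tree$phylo)
}

#' @rdname to_newick
#' @param path output path (conventionally \code{.nwk})
#' @export
write_newick <- function(tree, path) {
  writeLines(to_newick(tree), path)
  invisible(path)
}

#' Propagate subpopulation labels through cluster membership
#'
#' Cuts the tree into \code{k_top} clusters and assigns every unlabeled
#' sample the majority label among labeled samples sharing its cluster —
#' the "shared cluster membership" rule used to classify new cultivars
#' from a partially annotated reference set.  A cluster containing
#' unlabeled samples but no labeled ones (or a tied majority) yields
#' \code{"unknown"} and a report entry rather than an error.
#'
#' @param tree a \code{cluster_tree}
#' @param labels named character vector mapping a subset of leaf labels to
#'   subpopulation labels (e.g. \code{"Eastern"}, \code{"Western"})
#' @param k_top number of clusters to cut (default 3: outgroup plus two
#'   cultivar subpopulations)
#' @return object of class \code{"label_propagation"}: list with
#'   \code{labels} (complete named map), \code{table} (data frame
#'   \code{sample_id}, \code{assigned_subpop}, \code{evidence_count},
#'   \code{cluster}, \code{was_labeled}) and \code{unresolved_clusters}.
#' @export
propagate_labels <- function(tree, labels, k_top = 3L) {
  stopifnot(inherits(tree, "cluster_tree"))
  cl <- stats::cutree(tree$hclust, k = k_top)
  ids <- names(cl)
  known <- labels[intersect(names(labels), ids)]
  assigned <- character(length(ids))
  evidence <- integer(length(ids))
  names(assigned) <- ids
  unresolved <- integer(0)
  for (k in sort(unique(cl))) {
    members <- ids[cl == k]
    lab_here <- known[intersect(names(known), members)]
    tab <- sort(table(lab_here), decreasing = TRUE)
    if (length(tab) == 0L) {
      maj <- "unknown"; ev <- 0L
      if (any(!(members %in% names(known)))) unresolved <- c(unresolved, k)
    } else if (length(tab) > 1L && tab[1] == tab[2]) {
      maj <- "unknown"; ev <- 0L            # tied majority: refuse to guess
      unresolved <- c(unresolved, k)
    } else {
      maj <- names(tab)[1]; ev <- as.integer(tab[1])
    }
    assigned[members] <- maj
    evidence[match(members, ids)] <- ev
  }
  was_labeled <- ids %in% names(known)
  assigned[was_labeled] <- known[ids[was_labeled]]
  structure(
    list(
      labels = assigned,
      table = data.frame(sample_id = ids, assigned_subpop = unname(assigned),
                         evidence_count = evidence, cluster = unname(cl),
                         was_labeled = was_labeled, stringsAsFactors = FALSE),
      unresolved_clusters = unresolved,
      k_top = k_top
    ),
    class = "label_propagation"
  )
}

#' @export
print.label_propagation <- function(x, ...) {
  newly <- x$table[!x$table$was_labeled, ]
  tab <- table(newly$assigned_subpop)
  cat(sprintf("label propagation at k = %d: %d previously labeled, %d assigned\n",
              x$k_top, sum(x$table$was_labeled), nrow(newly)))
  for (nm in names(tab)) {
    cat(sprintf("  %s: %d (%s%%)\n", nm, tab[[nm]],
                format(pct(tab[[nm]], nrow(newly), digits = 2))))
  }
  if (length(x$unresolved_clusters)) {
    cat("  unresolved clusters:", paste(x$unresolved_clusters, collapse = ", "), "\n")
  }
  invisible(x)
}
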