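#' Configuration for the synthetic genotype generator
#'
#' Encodes the population structure the analysis pipeline assumes: two
#' cultivar subpopulations diverged by drift (Eastern/Western analogs), a
#' deeply diverged outgroup set of related species, clonal duplicates
#' (vegetative propagation makes some trees genetically identical),
#' seed-grown offspring (half the genome from a known mother, half from a
#' random population father), and GBS-like per-call read depth that drives
#' missingness.
#'
#' Subpopulation allele frequencies follow the Balding-Nichols
#' construction: for ancestral frequency \eqn{p} and divergence \eqn{F},
#' the subpopulation frequency is Beta\eqn{(p(1-F)/F, (1-p)(1-F)/F)}.
#' Ancestral frequencies are uniform on [0.05, 0.95] so markers carry
#' information and PIC selection has dynamic range.  Depth is Poisson by
#' default (a single parameter suffices for the pipeline's purposes);
#' \code{depth_dispersion} switches to negative binomial for overdispersed
#' coverage.
#'
#' @param n_east,n_west founder cultivars per subpopulation (30 each)
#' @param n_outgroup outgroup samples (10)
#' @param n_clones exact genotype copies of random cultivars, with
#'   independently re-drawn depth and missingness (5)
#' @param n_progeny seed offspring of random cultivar mothers (5)
#' @param n_markers number of biallelic SNPs (2000)
#' @param fst cultivar subpopulation divergence in (0, 1) (0.1)
#' @param outgroup_divergence outgroup divergence, must exceed \code{fst}
#'   (0.5)
#' @param depth_mean mean per-call read depth (30, a high-coverage design)
#' @param depth_dispersion optional negative-binomial size parameter;
#'   \code{NULL} keeps Poisson depth
#' @param missing_rate extra random missingness on top of the low-depth
#'   mask (0.02)
#' @param min_depth_call calls below this depth are missing (10, matching
#'   the QC protocol)
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   dataset
#' @return object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_east = 30L, n_west = 30L, n_outgroup = 10L,
                       n_clones = 5L, n_progeny = 5L, n_markers = 2000L,
                       fst = 0.1, outgroup_divergence = 0.5,
                       depth_mean = 30, depth_dispersion = NULL,
                       missing_rate = 0.02, min_depth_call = 10L,
                       seed = 1L) {
  cfg <- list(n_east = as.integer(n_east), n_west = as.integer(n_west),
              n_outgroup = as.integer(n_outgroup),
              n_clones = as.integer(n_clones),
              n_progeny = as.integer(n_progeny),
              n_markers = as.integer(n_markers),
              fst = fst, outgroup_divergence = outgroup_divergence,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              missing_rate = missing_rate,
              min_depth_call = as.integer(min_depth_call),
              seed = as.integer(seed))
  stopifnot(all(unlist(cfg[1:6]) >= 0L), cfg$n_markers >= 1L,
            fst > 0, fst < 1, outgroup_divergence > 0,
            outgroup_divergence < 1, fst < outgroup_divergence,
            depth_mean > 0, missing_rate >= 0, missing_rate < 1)
  if (cfg$n_east + cfg$n_west + cfg$n_outgroup == 0L) {
    stop("degenerate config: no samples")
  }
  if ((cfg$n_clones > 0L || cfg$n_progeny > 0L) &&
      cfg$n_east + cfg$n_west == 0L) {
    stop("clones/progeny need at least one cultivar founder")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a genotyping study
#'
#' Draws a complete synthetic study from a \code{\link{sim_config}}:
#' genotype matrix with depths and missingness, sample metadata (founder
#' cultivars carry known Eastern/Western labels, clones and progeny enter
#' as unlabeled survey samples, outgroup samples as outgroup), and a truth
#' map recording every sample's generating group, clone parent and
#' mother.  Fully deterministic given the config seed; the caller's RNG
#' state is untouched.
#'
#' @param cfg a \code{\link{sim_config}}
#' @return object of class \code{"sim_study"}: list with \code{gm}
#'   (\code{\link{genotype_matrix}}), \code{info} (metadata data frame),
#'   \code{truth} (data frame with \code{sample_id}, \code{group},
#'   \code{role}, \code{clone_parent}, \code{mother}), \code{config}.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    m <- cfg$n_markers
    p_anc <- stats::runif(m, 0.05, 0.95)
    bn <- function(p, f) stats::rbeta(m, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    p_sub <- list(east = bn(p_anc, cfg$fst),
                  west = bn(p_anc, cfg$fst),
                  outgroup = bn(p_anc, cfg$outgroup_divergence))

    draw <- function(n, p) {
      if (n == 0L) return(matrix(integer(0), 0L, m))
      matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
    }
    founders <- rbind(draw(cfg$n_east, p_sub$east),
                      draw(cfg$n_west, p_sub$west))
    f_group <- rep(c("east", "west"), c(cfg$n_east, cfg$n_west))
    f_ids <- c(sprintf("East_%02d", seq_len(cfg$n_east)),
               sprintf("West_%02d", seq_len(cfg$n_west)))
    out_calls <- draw(cfg$n_outgroup, p_sub$outgroup)
    out_ids <- sprintf("Out_%02d", seq_len(cfg$n_outgroup))

    clone_parent <- if (cfg$n_clones > 0L)
      sample(seq_along(f_ids), cfg$n_clones, replace = TRUE) else integer(0)
    clone_calls <- founders[clone_parent, , drop = FALSE]
    clone_ids <- sprintf("Clone_%02d", seq_len(cfg$n_clones))

    mothers <- if (cfg$n_progeny > 0L)
      sample(seq_along(f_ids), cfg$n_progeny, replace = TRUE) else integer(0)
    prog_calls <- matrix(integer(0), 0L, m)
    if (cfg$n_progeny > 0L) {
      prog_calls <- t(vapply(mothers, function(mo) {
        maternal <- stats::rbinom(m, 1L, founders[mo, ] / 2)
        paternal <- stats::rbinom(m, 1L, p_sub[[f_group[mo]]])
        maternal + paternal
      }, integer(m)))
    }
    prog_ids <- sprintf("Progeny_%02d", seq_len(cfg$n_progeny))

    calls <- rbind(founders, out_calls, clone_calls, prog_calls)
    ids <- c(f_ids, out_ids, clone_ids, prog_ids)
    n <- length(ids)

    depths <- if (is.null(cfg$depth_dispersion)) {
      matrix(stats::rpois(n * m, cfg$depth_mean), n, m)
    } else {
      matrix(stats::rnbinom(n * m, mu = cfg$depth_mean,
                            size = cfg$depth_dispersion), n, m)
    }
    calls[depths < cfg$min_depth_call] <- NA_integer_
    if (cfg$missing_rate > 0) {
      extra <- stats::runif(n * m) < cfg$missing_rate
      calls[extra] <- NA_integer_
    }

    variants <- data.frame(
      chrom = "chr1", pos = 1000L * seq_len(m),
      id = sprintf("snp%05d", seq_len(m)),
      ref = "A", alt = "C", stringsAsFactors = FALSE
    )
    gm <- genotype_matrix(calls, depths, variants, samples = ids)

    group <- c(f_group, rep("outgroup", cfg$n_outgroup),
               f_group[clone_parent], f_group[mothers])
    role <- rep(c("founder", "outgroup", "clone", "progeny"),
                c(cfg$n_east + cfg$n_west, cfg$n_outgroup,
                  cfg$n_clones, cfg$n_progeny))
    truth <- data.frame(
      sample_id = ids, group = group, role = role,
      clone_parent = c(rep(NA_character_, length(f_ids) + length(out_ids)),
                       f_ids[clone_parent],
                       rep(NA_character_, cfg$n_progeny)),
      mother = c(rep(NA_character_, n - cfg$n_progeny), f_ids[mothers]),
      stringsAsFactors = FALSE
    )
    info <- data.frame(
      sample_id = ids,
      set_label = c(rep("cultivar", length(f_ids)),
                    rep("outgroup", length(out_ids)),
                    rep("survey", cfg$n_clones + cfg$n_progeny)),
      subpop_label = c(ifelse(f_group == "east", "Eastern", "Western"),
                       rep(NA_character_,
                           length(out_ids) + cfg$n_clones + cfg$n_progeny)),
      latitude = NA_real_, longitude = NA_real_,
      stringsAsFactors = FALSE
    )
    structure(list(gm = gm, info = info, truth = truth, config = cfg,
                   subpop_freqs = p_sub, ancestral_freqs = p_anc),
              class = "sim_study")
  })
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "sim_study (seed %d): %d east + %d west + %d outgroup founders, %d clones, %d progeny; %d markers\n",
    x$config$seed, x$config$n_east, x$config$n_west, x$config$n_outgroup,
    x$config$n_clones, x$config$n_progeny, x$config$n_markers))
  print(x$gm)
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Standard formats, same dialects the pipeline reads back: one VCF per
#' sample set, a metadata TSV and a truth-map JSON.
#'
#' @param sim a \code{\link{simulate_genotypes}} result
#' @param dir output directory (created if needed)
#' @return named list of file paths, invisibly.
#' @export
write_sim_study <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(metadata = file.path(dir, "samples.tsv"),
                truth = file.path(dir, "truth.json"))
  by_set <- split(sim$info$sample_id, sim$info$set_label)
  for (set in names(by_set)) {
    p <- file.path(dir, paste0(set, ".vcf"))
    write_vcf(sim$gm[by_set[[set]], ], p)
    paths[[set]] <- p
  }
  utils::write.table(sim$info, paths$metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write the hand-constructed toy VCF fixtures
#'
#' Three tiny datasets with fully known outcomes, used across the test
#' suite, each with a JSON sidecar of expected results:
#' \itemize{
#'   \item \code{qc_cascade.vcf}: 6 samples x 8 variants built so the QC
#'     cascade drops exactly 2 variants at the first missingness stage
#'     (V7, V8), 1 sample at the sample stage (S6), and 2 more variants at
#'     the final stage (V5 by recomputed missingness, V6 as
#'     multi-allelic), ending at 5 samples x 4 variants.  V1 and V2 are
#'     missing only in S6, so they pass the final missingness bound only
#'     if it is recomputed after S6 is gone.
#'   \item \code{depth_mask.vcf}: 2 samples x 2 variants with depth grid
#'     rows (30, 9) and (10, 0); masking at 10 blanks exactly the second
#'     variant in both samples.
#'   \item \code{merge_a.vcf} / \code{merge_b.vcf}: 3 + 2 samples on a
#'     5-variant panel, with merge_b lacking 2 panel variants, so merging
#'     creates exactly 4 missing cells.
#' }
#'
#' @param outdir writable directory (created if needed)
#' @return named list of file paths, invisibly.
#' @export
make_toy_vcf_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  samples <- paste0("S", 1:6)
  # dosages: rows = samples S1..S6, cols = V1..V8
  calls <- rbind(
    c(0, 1, 0, 2, 1, 0, 1, 0),
    c(1, 0, 1, 1, 0, 1, 0, 1),
    c(2, 1, 0, 0, 1, 2, 1, 0),
    c(1, 2, 1, 1, 2, 1, 0, 1),
    c(0, 1, 2, 0, 1, 0, 1, 2),
    c(1, 0, 1, 2, 0, 1, 0, 1)
  )
  depths <- matrix(30L, 6, 8)
  depths[1:3, 7] <- 5L    # V7 missing in 3/6 -> stage-2 drop (0.5 > 0.4)
  depths[1:3, 8] <- 8L    # V8 likewise
  depths[6, 1] <- 4L      # S6 missing at V1, V2 -> 2/6 > 0.3 -> stage-3 drop
  depths[6, 2] <- 6L
  depths[4, 5] <- 9L      # V5: 1/5 = 0.2 >= 0.1 after S6 is gone -> stage-4 drop
  variants <- data.frame(
    chrom = "chr1", pos = 100L * (1:8), id = paste0("V", 1:8),
    ref = "A", alt = c("C", "C", "C", "C", "C", "C,G", "C", "C"),
    stringsAsFactors = FALSE
  )
  qc_gm <- genotype_matrix(calls, depths, variants, samples)
  paths <- list(
    qc_vcf = file.path(outdir, "qc_cascade.vcf"),
    qc_expected = file.path(outdir, "qc_cascade.expected.json"),
    depth_vcf = file.path(outdir, "depth_mask.vcf"),
    depth_expected = file.path(outdir, "depth_mask.expected.json"),
    merge_a = file.path(outdir, "merge_a.vcf"),
    merge_b = file.path(outdir, "merge_b.vcf"),
    merge_expected = file.path(outdir, "merge.expected.json")
  )
  write_vcf(qc_gm, paths$qc_vcf)
  jsonlite::write_json(list(
    final_samples = 5, final_variants = 4,
    final_variant_ids = paste0("V", 1:4),
    final_sample_ids = paste0("S", 1:5),
    stage2_dropped_variants = c("V7", "V8"),
    stage3_dropped_samples = "S6",
    stage4_dropped_variants = c("V5", "V6")
  ), paths$qc_expected, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  dm_gm <- genotype_matrix(
    calls = rbind(c(0, 1), c(2, 1)),
    depths = rbind(c(30L, 9L), c(10L, 0L)),
    variants = data.frame(chrom = "chr1", pos = c(10L, 20L),
                          id = c("D1", "D2"), ref = "A", alt = "G",
                          stringsAsFactors = FALSE),
    samples = c("S1", "S2")
  )
  write_vcf(dm_gm, paths$depth_vcf)
  jsonlite::write_json(list(
    min_depth = 10,
    missing_cells = list(c("S1", "D2"), c("S2", "D2"))
  ), paths$depth_expected, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  pvar <- data.frame(chrom = "chr1", pos = 10L * (1:5),
                     id = paste0("P", 1:5), ref = "A", alt = "T",
                     stringsAsFactors = FALSE)
  gm_a <- genotype_matrix(matrix(c(0, 1, 2, 1, 0,
                                   1, 1, 0, 2, 1,
                                   2, 0, 1, 0, 2), 3, 5, byrow = TRUE),
                          matrix(25L, 3, 5), pvar, paste0("A", 1:3))
  gm_b <- genotype_matrix(matrix(c(1, 0, 2,
                                   0, 2, 1), 2, 3, byrow = TRUE),
                          matrix(25L, 2, 3),
                          pvar[c(1, 2, 4), ], paste0("B", 1:2))
  write_vcf(gm_a, paths$merge_a)
  write_vcf(gm_b, paths$merge_b)
  jsonlite::write_json(list(
    panel_ids = paste0("P", 1:5),
    absent_in_b = c("P3", "P5"),
    expected_missing_cells = 4
  ), paths$merge_expected, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
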