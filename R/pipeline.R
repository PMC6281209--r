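#' Configuration for a full study run
#'
#' Collects input paths and every threshold of the workflow.  The
#' defaults are the study protocol's printed values: depth mask at 10x,
#' first-pass variant missingness bound 0.4, sample missingness bound
#' 0.3, final variant missingness bound 0.1, Hardy-Weinberg exact p-value
#' floor 1e-6, LD pruning at r-squared 0.1, panel PIC threshold 0.37, and
#' a 3-way top-level tree cut (outgroup / two cultivar subpopulations).
#'
#' @param vcf named list of VCF paths, names among \code{cultivar},
#'   \code{outgroup}, \code{survey}; \code{cultivar} is required
#' @param metadata path to the sample metadata TSV
#'   (\code{\link{read_sample_info}} dialect)
#' @param outdir output directory for the report bundle
#' @param seed integer seed used for every stochastic step (Mantel
#'   permutations)
#' @param min_depth,variant_miss_max_stage1,sample_miss_max,variant_miss_max_stage2,hwe_p_min
#'   QC cascade thresholds, see \code{\link{run_qc_cascade}}
#' @param r2_max,ld_window,ld_step LD pruning parameters, see
#'   \code{\link{ld_prune}}
#' @param pic_min panel PIC threshold, see \code{\link{select_panel}}
#' @param k_top clusters for label propagation (3)
#' @param k_survey deeper cut used for the survey-sample composition
#'   table (6)
#' @param n_perm Mantel permutations (999)
#' @return object of class \code{"study_config"}.
#' @export
study_config <- function(vcf, metadata, outdir, seed,
                         min_depth = 10L,
                         variant_miss_max_stage1 = 0.4,
                         sample_miss_max = 0.3,
                         variant_miss_max_stage2 = 0.1,
                         hwe_p_min = 1e-6,
                         r2_max = 0.1, ld_window = 50L, ld_step = 5L,
                         pic_min = 0.37, k_top = 3L, k_survey = 6L,
                         n_perm = 999L) {
  stopifnot(is.list(vcf), "cultivar" %in% names(vcf))
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "study_config")
}

#' Run the full cultivar-identification workflow
#'
#' Executes, in order: per-set genotype QC; merge of all sets onto the
#' cultivar set's surviving variants; (1-IBS) distance matrix; Ward
#' clustering with outgroup orientation and Newick export; propagation of
#' known subpopulation labels to unlabeled cultivars and survey samples;
#' LD pruning and PIC-based panel selection; panel distance matrix and
#' fidelity assessment (lower-triangle Pearson correlation plus seeded
#' Mantel test against the full-set matrix); and a cluster-composition
#' table of the survey samples at a deeper cut.  All artifacts are
#' written under \code{cfg$outdir} with a MANIFEST of completed stages
#' and a provenance JSON of thresholds and seed, so a failed run leaves
#' its partial outputs attributable.
#'
#' @param cfg a \code{\link{study_config}}
#' @return object of class \code{"palm_study"} with elements \code{qc}
#'   (per-set reports), \code{gm} (merged matrix), \code{dist_full},
#'   \code{tree}, \code{assignment}, \code{panel}, \code{dist_panel},
#'   \code{fidelity}, \code{composition}, \code{config}, \code{files}.
#' @export
run_full_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  if (!file.exists(cfg$metadata)) {
    stop("config error: metadata file not found: ", cfg$metadata)
  }
  for (p in unlist(cfg$vcf)) {
    if (!file.exists(p)) stop("config error: VCF not found: ", p)
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  done <- character(0)
  manifest <- file.path(cfg$outdir, "MANIFEST")
  mark <- function(stage) {
    done <<- c(done, stage)
    writeLines(done, manifest)
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[%s] done", name))
    mark(name)
    res
  }
  files <- list()

  info <- stage("read_metadata", read_sample_info(cfg$metadata))

  sets <- stage("read_vcf", lapply(cfg$vcf, read_vcf))

  qc <- stage("qc_cascade", lapply(sets, function(gm) {
    run_qc_cascade(gm,
                   min_depth = cfg$min_depth,
                   variant_miss_max_stage1 = cfg$variant_miss_max_stage1,
                   sample_miss_max = cfg$sample_miss_max,
                   variant_miss_max_stage2 = cfg$variant_miss_max_stage2,
                   hwe_p_min = cfg$hwe_p_min)
  }))
  for (set in names(qc)) {
    f <- file.path(cfg$outdir, paste0("qc_", set, ".json"))
    write_qc_report(qc[[set]]$report, f)
    files[[paste0("qc_", set)]] <- f
  }

  # Reference marker set = cultivar variants surviving QC; other sets are
  # projected onto it (samples lacking a site are missing there).
  merged <- stage("merge", {
    ref_panel <- qc$cultivar$gm$variants
    merge_on_panel(lapply(qc, `[[`, "gm"), ref_panel)
  })

  dist_full <- stage("ibs_distance", ibs_distance(merged))
  files$dist_full <- file.path(cfg$outdir, "distances_full.tsv")
  write_distance_tsv(dist_full, files$dist_full)

  tree <- stage("ward_cluster", ward_cluster(dist_full))
  out_ids <- intersect(info$sample_id[info$set_label == "outgroup"],
                       merged$samples)
  if (length(out_ids)) {
    tree <- stage("orient_by_outgroup", orient_by_outgroup(tree, out_ids))
  }
  files$tree <- file.path(cfg$outdir, "tree.nwk")
  write_newick(tree, files$tree)

  known <- info$subpop_label[match(merged$samples, info$sample_id)]
  names(known) <- merged$samples
  known <- known[!is.na(known) & known %in% c("Eastern", "Western")]
  assignment <- stage("propagate_labels",
                      propagate_labels(tree, known, k_top = cfg$k_top))
  files$labels <- file.path(cfg$outdir, "labels.tsv")
  utils::write.table(assignment$table, files$labels, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  pruned <- stage("ld_prune",
                  ld_prune(merged, r2_max = cfg$r2_max,
                           window = cfg$ld_window, step = cfg$ld_step))
  panel <- stage("select_panel", select_panel(
    merged, pruned, pic_min = cfg$pic_min,
    provenance = list(r2_max = cfg$r2_max, window = cfg$ld_window,
                      step = cfg$ld_step, seed = cfg$seed)))
  files$panel <- file.path(cfg$outdir, "panel.tsv")
  write_panel(panel, files$panel)

  fidelity <- NULL
  dist_panel <- NULL
  if (length(panel) >= 2L) {
    dist_panel <- stage("panel_distance", {
      cols <- match(paste(panel$variants$chrom, panel$variants$pos),
                    paste(merged$variants$chrom, merged$variants$pos))
      ibs_distance(merged[, cols])
    })
    files$dist_panel <- file.path(cfg$outdir, "distances_panel.tsv")
    write_distance_tsv(dist_panel, files$dist_panel)
    fidelity <- stage("fidelity", {
      mt <- mantel_test(dist_full, dist_panel, n_perm = cfg$n_perm,
                        seed = cfg$seed)
      c(list(pearson_r = matrix_correlation(dist_full, dist_panel)), mt)
    })
    files$fidelity <- file.path(cfg$outdir, "fidelity.json")
    jsonlite::write_json(fidelity, files$fidelity, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    warning("panel too small for fidelity assessment; stage skipped")
  }

  survey_ids <- intersect(info$sample_id[info$set_label == "survey"],
                          merged$samples)
  composition <- NULL
  if (length(survey_ids)) {
    composition <- stage("cluster_composition", {
      k <- min(cfg$k_survey, length(merged$samples) - 1L)
      groups <- stats::cutree(tree$hclust, k = k)
      report_cluster_composition(groups, survey_ids)
    })
    files$composition <- file.path(cfg$outdir, "composition.tsv")
    utils::write.table(composition, files$composition, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  prov <- cfg[setdiff(names(cfg), c("vcf", "metadata", "outdir"))]
  prov$vcf <- lapply(cfg$vcf, normalizePath)
  files$provenance <- file.path(cfg$outdir, "provenance.json")
  jsonlite::write_json(prov, files$provenance, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  mark("provenance")

  structure(
    list(qc = lapply(qc, `[[`, "report"), gm = merged,
         dist_full = dist_full, tree = tree, assignment = assignment,
         panel = panel, dist_panel = dist_panel, fidelity = fidelity,
         composition = composition, config = cfg, files = files),
    class = "palm_study"
  )
}

#' Cluster composition of survey samples
#'
#' Tabulates, per cluster/group, how many survey samples it holds and
#' what whole-number percentage of all survey samples that is (counts are
#' kept alongside so the rounding loses nothing).
#'
#' @param labels named vector mapping sample ids to a group (cluster id
#'   or subpopulation label); must cover \code{survey_ids}
#' @param survey_ids character vector of survey sample ids
#' @param metadata optional data frame with \code{sample_id} plus extra
#'   columns (e.g. municipality) to cross-tabulate
#' @return data frame with \code{group}, \code{n_survey},
#'   \code{pct_survey}, ordered by decreasing count.
#' @export
report_cluster_composition <- function(labels, survey_ids, metadata = NULL) {
  miss <- setdiff(survey_ids, names(labels))
  if (length(miss)) {
    stop("labels do not cover survey ids: ", paste(miss, collapse = ", "))
  }
  grp <- labels[survey_ids]
  tab <- sort(table(grp), decreasing = TRUE)
  out <- data.frame(group = names(tab), n_survey = as.integer(tab),
                    pct_survey = pct(as.integer(tab), length(survey_ids)),
                    stringsAsFactors = FALSE)
  if (!is.null(metadata) && "sample_id" %in% names(metadata)) {
    extra <- setdiff(names(metadata), "sample_id")
    for (col in extra) {
      xt <- table(grp, metadata[[col]][match(survey_ids, metadata$sample_id)])
      out[[paste0("by_", col)]] <- apply(
        xt[match(out$group, rownames(xt)), , drop = FALSE], 1,
        function(r) paste(colnames(xt)[r > 0], r[r > 0], sep = ":",
                          collapse = ","))
    }
  }
  rownames(out) <- NULL
  out
}

#' @export
print.palm_study <- function(x, ...) {
  cat("palm_study run\n")
  for (set in names(x$qc)) {
    r <- x$qc[[set]]
    cat(sprintf("  QC [%s]: %d -> %d samples, %d -> %d variants\n", set,
                r$samples_in[1], r$samples_out[nrow(r)],
                r$variants_in[1], r$variants_out[nrow(r)]))
  }
  cat(sprintf("  merged: %d samples x %d variants\n",
              n_samples(x$gm), n_variants(x$gm)))
  print(x$tree)
  newly <- x$assignment$table[!x$assignment$table$was_labeled, ]
  newly <- newly[newly$assigned_subpop %in% c("Eastern", "Western"), ]
  if (nrow(newly)) {
    tb <- table(newly$assigned_subpop)
    cat(sprintf("  newly assigned: %s\n",
                paste(sprintf("%s %d (%.2f%%)", names(tb), tb,
                              100 * as.integer(tb) / nrow(newly)),
                      collapse = ", ")))
  }
  cat(sprintf("  panel: %d markers", length(x$panel)))
  if (!is.null(x$fidelity)) {
    cat(sprintf("; fidelity R = %.3f (Mantel r = %.3f, p = %.4g, %d perms)",
                x$fidelity$pearson_r, x$fidelity$mantel_r,
                x$fidelity$mantel_p, x$fidelity$n_perm))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.palm_study <- function(object, ...) {
  print(object)
  if (!is.null(object$composition)) {
    cat("  survey composition:\n")
    print(object$composition)
  }
  invisible(object)
}

#' @export
plot.palm_study <- function(x, ...) {
  plot(x$tree, ...)
}
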