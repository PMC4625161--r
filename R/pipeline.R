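#' Pipeline configuration
#'
#' Bundles every stage threshold with its study default: call-rate 0.95,
#' Hardy-Weinberg alpha 0.001 in controls, LD pruning at r-squared 0.75,
#' 10 eigenvectors with sigma-6 outlier removal over at most 10 iterations,
#' theoretical p ceiling 1e-5 with a 1e6 permutation budget, and the
#' classifier's R threshold of 3.
#'
#' @param call_rate,hwe_alpha,r2,pca_k,pca_sigma,pca_max_iter,p_ceiling,max_perms,r_min
#'   Stage thresholds (see Description for defaults).
#' @param weight_form,pooled_panel Classifier options passed to
#'   [fit_weight_model()].
#' @param seed Integer seed governing every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(call_rate = 0.95, hwe_alpha = 0.001, r2 = 0.75,
                            pca_k = 10L, pca_sigma = 6, pca_max_iter = 10L,
                            p_ceiling = 1e-5, max_perms = 1e6,
                            r_min = 3, weight_form = "freq",
                            pooled_panel = FALSE, seed = 1L) {
  cfg <- list(call_rate = call_rate, hwe_alpha = hwe_alpha, r2 = r2,
              pca_k = as.integer(pca_k), pca_sigma = pca_sigma,
              pca_max_iter = as.integer(pca_max_iter),
              p_ceiling = p_ceiling, max_perms = max_perms, r_min = r_min,
              weight_form = weight_form, pooled_panel = pooled_panel,
              seed = as.integer(seed))
  stopifnot(cfg$call_rate > 0, cfg$call_rate <= 1,
            cfg$hwe_alpha > 0, cfg$hwe_alpha < 1,
            cfg$r2 > 0, cfg$p_ceiling > 0, cfg$max_perms >= 1,
            cfg$r_min >= 0)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full association-and-classification pipeline
#'
#' Chains the stages in study order: sample call-rate QC, per-comparison
#' Hardy-Weinberg filtering in controls, one-vs-rest allelic association,
#' adaptive permutation of the candidates, the true-positive panel filter,
#' LD pruning of the panel, PCA on the pruned panel with pairwise
#' eigenvector group tests, classifier fit and cohort classification, and
#' (when gene intervals are supplied) genic annotation of the panel.
#' Each stage's tables are written as TSV under a numbered subdirectory of
#' `out_dir` when given, and a log line with counts and seed is recorded.
#'
#' @param table Input [geno_table()] with V/P/K group labels.
#' @param config A [pipeline_config()].
#' @param genes Optional gene intervals ([read_bed_intervals()]).
#' @param out_dir Optional run directory; created if needed.
#' @return A list with elements `qc`, `association`, `panel`, `pc_model`,
#'   `group_tests`, `weight_model`, `classification`, `annotation`
#'   (`NULL` without `genes`), and `log` (tibble of stage messages).
#' @export
run_prakriti_pipeline <- function(table, config = pipeline_config(),
                                  genes = NULL, out_dir = NULL) {
  stopifnot(inherits(table, "geno_table"),
            inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      stage = stage, message = msg, seed = config$seed)
  }
  emit <- function(stage_dir, name, df) {
    if (is.null(out_dir)) return(invisible())
    d <- file.path(out_dir, stage_dir)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(df, file.path(d, paste0(name, ".tsv")))
  }

  qc <- sample_call_rate_filter(table, threshold = config$call_rate)
  note("qc", sprintf("%d of %d samples pass call rate >= %g",
                     n_samples(qc$table), n_samples(table), config$call_rate))
  emit("01_qc", "call_rate", qc$report)

  assoc <- assoc_scan(qc$table, hwe_alpha = config$hwe_alpha,
                      max_perms = config$max_perms,
                      perm_p_max = config$p_ceiling, seed = config$seed)
  note("assoc", sprintf("%d association records; %d permuted",
                        nrow(assoc), sum(!is.na(assoc$p_empirical))))
  emit("02_assoc", "association", assoc)

  tp <- true_positive_filter(assoc, p_ceiling = config$p_ceiling,
                             max_perms = config$max_perms)
  note("panel", sprintf("%d records pass; %d distinct panel markers",
                        nrow(tp$records), length(tp$panel)))
  emit("03_panel", "panel_records", tp$records)

  result <- list(qc = qc, association = assoc, panel = tp,
                 pc_model = NULL, group_tests = NULL, weight_model = NULL,
                 classification = NULL, annotation = NULL)

  if (length(tp$panel) >= 2L) {
    panel_tab <- subset_geno(qc$table, markers = tp$panel)
    pruned <- ld_prune(panel_tab, r2_threshold = config$r2)
    note("pca", sprintf("panel LD pruning kept %d of %d markers",
                        length(pruned$kept), length(tp$panel)))
    k <- min(config$pca_k, n_samples(panel_tab) - 1L)
    pc <- pca_fit(pruned$table, k = k)
    result$pc_model <- pc
    result$group_tests <- eigenvector_group_test(pc)
    emit("04_pca", "eigenvectors", tidy(pc))
    emit("04_pca", "group_tests", result$group_tests)
  } else {
    note("pca", "panel too small for PCA; stage skipped")
  }

  if (length(tp$panel) >= 1L) {
    panels <- split(tp$records$marker,
                    substr(tp$records$comparison, 1L, 1L))
    for (g in c("V", "P", "K")) {
      if (is.null(panels[[g]]) || !length(panels[[g]])) {
        panels[[g]] <- tp$panel   # fall back to the pooled panel
      }
    }
    wm <- fit_weight_model(qc$table, panels[c("V", "P", "K")],
                           weight_form = config$weight_form,
                           pooled_panel = config$pooled_panel,
                           r_min = config$r_min)
    cls <- classify_cohort(wm, qc$table)
    result$weight_model <- wm
    result$classification <- cls
    assigned <- sum(cls$calls$call != "UNASSIGNED")
    note("classify", sprintf("%d of %d samples assigned (%.1f%%)",
                             assigned, nrow(cls$calls),
                             100 * assigned / max(1L, nrow(cls$calls))))
    emit("05_classify", "calls", cls$calls)
    emit("05_classify", "summary", cls$summary)
  } else {
    note("classify", "empty panel; classifier stage skipped")
  }

  if (!is.null(genes) && length(tp$panel)) {
    mk <- qc$table$markers
    ann <- annotate_markers(mk[mk$marker %in% tp$panel, ], genes)
    result$annotation <- ann
    note("annotate", sprintf("%d genic of %d panel markers",
                             sum(ann$status == "genic"), nrow(ann)))
    emit("06_annotate", "annotation", ann)
  }

  result$log <- dplyr::bind_rows(log)
  emit("00_log", "log", result$log)
  result
}
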