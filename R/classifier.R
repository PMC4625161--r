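#' Fit the genotype-frequency weight classifier
#'
#' For each constitutional-type group p and each marker of that group's
#' associated panel, the weight of genotype state g is its observed
#' within-group frequency `f_p(g)` (missing genotypes excluded). A
#' sample's unstandardized group score is the sum of these weights over
#' the group's panel; standardization constants (mean and SD of the
#' unstandardized score) are computed over all N training samples, so the
#' same constants also score external samples.
#'
#' @param table Training [geno_table()] with group labels V/P/K.
#' @param panels Named list of character vectors: the associated marker
#'   panel of each group, e.g. `list(V = ..., P = ..., K = ...)` (normally
#'   the per-comparison output of [true_positive_filter()]). Panels may
#'   overlap.
#' @param weight_form `"freq"` (default) uses the raw frequency as the
#'   weight; `"logfreq"` uses `log(f + 1e-3)`.
#' @param pooled_panel If `TRUE`, every group is scored on the pooled union
#'   of the three panels instead of its own panel.
#' @param r_min Assignment threshold on the representative statistic
#'   (default 3).
#' @return A `weight_model`: frequency tables (3 states x markers, per
#'   group), panel lists, standardization means/SDs, `r_min`.
#' @export
fit_weight_model <- function(table, panels, weight_form = c("freq", "logfreq"),
                             pooled_panel = FALSE, r_min = 3) {
  stopifnot(inherits(table, "geno_table"),
            all(c("V", "P", "K") %in% names(panels)))
  weight_form <- match.arg(weight_form)
  if (pooled_panel) {
    pool <- unique(unlist(panels))
    panels <- list(V = pool, P = pool, K = pool)
  }
  panels <- purrr::map(panels[c("V", "P", "K")], unique)
  all_panel <- unique(unlist(panels))
  missing_mk <- setdiff(all_panel, table$markers$marker)
  if (length(missing_mk)) {
    stop("panel markers absent from table: ",
         paste(missing_mk, collapse = ", "), call. = FALSE)
  }
  groups <- c("V", "P", "K")
  freq <- purrr::map(groups, function(grp) {
    ids <- group_samples(table, grp)
    if (!length(ids)) stop("no training samples in group ", grp, call. = FALSE)
    g <- subset_geno(table, samples = ids, markers = panels[[grp]])$genotypes
    f <- apply(g, 2L, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) stop("panel marker with no genotyped training sample",
                           call. = FALSE)
      tabulate(x + 1L, 3L) / length(x)
    })
    rownames(f) <- c("g0", "g1", "g2")
    f
  })
  names(freq) <- groups

  model <- structure(list(panels = panels, freq = freq,
                          weight_form = weight_form,
                          mean = c(V = 0, P = 0, K = 0),
                          sd = c(V = 1, P = 1, K = 1),
                          r_min = r_min, n_train = n_samples(table)),
                     class = "weight_model")
  raw <- raw_weights(model, table, warn_unseen = FALSE)
  mu <- colMeans(raw)
  sd <- apply(raw, 2L, stats::sd)
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    stop("degenerate standardization: training score SD is zero",
         call. = FALSE)
  }
  model$mean <- mu
  model$sd <- sd
  model
}

#' @export
print.weight_model <- function(x, ...) {
  cat("<weight_model>\n")
  cat("  panel sizes:",
      paste(sprintf("%s=%d", names(x$panels), lengths(x$panels)),
            collapse = ", "), "\n")
  cat(sprintf("  weight form: %s; R threshold: %g; trained on %d samples\n",
              x$weight_form, x$r_min, x$n_train))
  invisible(x)
}

# unstandardized group scores, samples x 3; missing panel markers are
# skipped and the total rescaled by panel_size / n_non_missing
raw_weights <- function(model, table, warn_unseen = TRUE) {
  groups <- c("V", "P", "K")
  wfun <- if (model$weight_form == "logfreq") {
    function(f) log(f + 1e-3)
  } else {
    identity
  }
  unseen <- 0L
  out <- vapply(groups, function(grp) {
    mk <- model$panels[[grp]]
    g <- subset_geno(table, markers = mk)$genotypes
    W <- wfun(model$freq[[grp]])
    w_obs <- matrix(NA_real_, nrow(g), ncol(g))
    for (j in seq_len(ncol(g))) {
      gj <- g[, j]
      w_obs[, j] <- W[gj + 1L, j]
      unseen <<- unseen + sum(model$freq[[grp]][gj[!is.na(gj)] + 1L, j] == 0)
    }
    n_obs <- rowSums(!is.na(w_obs))
    if (any(n_obs == 0L)) {
      stop("sample(s) with no genotyped panel marker for group ", grp,
           call. = FALSE)
    }
    rowSums(w_obs, na.rm = TRUE) * length(mk) / n_obs
  }, numeric(n_samples(table)))
  if (warn_unseen && unseen > 0L) {
    warning(sprintf(paste0("%d genotype observation(s) at states never seen",
                           " in a group's training data (weight 0)"),
                    unseen))
  }
  colnames(out) <- groups
  out
}

#' Standardized group scores for samples
#'
#' @param model A [fit_weight_model()] fit.
#' @param table A [geno_table()] sharing the panel markers.
#' @return A tibble `sample`, `Z_V`, `Z_P`, `Z_K`.
#' @export
score_samples <- function(model, table) {
  stopifnot(inherits(model, "weight_model"), inherits(table, "geno_table"))
  raw <- raw_weights(model, table)
  z <- sweep(sweep(raw, 2L, model$mean, "-"), 2L, model$sd, "/")
  tibble::tibble(sample = table$samples$sample,
                 Z_V = z[, "V"], Z_P = z[, "P"], Z_K = z[, "K"])
}

#' Classify samples into a dominant constitutional type
#'
#' From the standardized scores, the six ordered score differences
#' `D_pq = Z_p - Z_q` are formed; the representative statistic of group p
#' is the product of its two differences, `R_p = D_pq * D_pr`. A sample is
#' assigned to group p iff both of p's differences are positive (at most
#' one group can satisfy this) and `R_p >= r_min`; otherwise it is
#' `UNASSIGNED` with a reason code (`negative_delta` when no group has both
#' differences positive, `below_threshold` when the dominant group's R
#' falls short).
#'
#' @inheritParams score_samples
#' @param r_min Override of the model's assignment threshold.
#' @return A `prakriti_calls` tibble: per sample the three Z scores, six
#'   deltas (`d_VP`, `d_VK`, `d_PV`, `d_PK`, `d_KV`, `d_KP`), three R
#'   statistics, `call` (`"V"`, `"P"`, `"K"` or `"UNASSIGNED"`), `reason`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_markers = 60, frac_associated = 0.5,
#'                                   effect_delta = 0.3, fst = 0, seed = 7))
#' panels <- split(sim$truth$markers$marker[!is.na(sim$truth$markers$affected_group)],
#'                 sim$truth$markers$affected_group[!is.na(sim$truth$markers$affected_group)])
#' fit <- fit_weight_model(sim$table, panels)
#' calls <- classify_samples(fit, sim$table)
#' dplyr::count(calls, call)
#' @export
classify_samples <- function(model, table, r_min = NULL) {
  sc <- score_samples(model, table)
  if (is.null(r_min)) r_min <- model$r_min
  res <- dplyr::mutate(
    sc,
    d_VP = .data$Z_V - .data$Z_P, d_VK = .data$Z_V - .data$Z_K,
    d_PV = .data$Z_P - .data$Z_V, d_PK = .data$Z_P - .data$Z_K,
    d_KV = .data$Z_K - .data$Z_V, d_KP = .data$Z_K - .data$Z_P,
    R_V = .data$d_VP * .data$d_VK,
    R_P = .data$d_PV * .data$d_PK,
    R_K = .data$d_KV * .data$d_KP)
  both_pos <- cbind(V = res$d_VP > 0 & res$d_VK > 0,
                    P = res$d_PV > 0 & res$d_PK > 0,
                    K = res$d_KV > 0 & res$d_KP > 0)
  stopifnot(all(rowSums(both_pos) <= 1L))   # algebraic invariant
  dom <- apply(both_pos, 1L, function(x) {
    if (any(x)) c("V", "P", "K")[which(x)] else NA_character_
  })
  R <- cbind(V = res$R_V, P = res$R_P, K = res$R_K)
  r_dom <- ifelse(is.na(dom), NA_real_,
                  R[cbind(seq_len(nrow(R)), match(dom, colnames(R)))])
  res$call <- ifelse(!is.na(dom) & r_dom >= r_min, dom, "UNASSIGNED")
  res$reason <- dplyr::case_when(
    res$call != "UNASSIGNED" ~ "assigned",
    is.na(dom) ~ "negative_delta",
    TRUE ~ "below_threshold")
  class(res) <- c("prakriti_calls", class(res))
  res
}

#' Classify a whole cohort and summarize
#'
#' @inheritParams classify_samples
#' @return A list with `calls` (the [classify_samples()] tibble) and
#'   `summary` (counts and fraction per call, including `UNASSIGNED`).
#' @export
classify_cohort <- function(model, table, r_min = NULL) {
  calls <- classify_samples(model, table, r_min = r_min)
  summary <- dplyr::mutate(dplyr::count(calls, .data$call),
                           fraction = .data$n / sum(.data$n))
  list(calls = calls, summary = summary)
}

#' @rdname tidy.weight_model
#' @param x A `weight_model`.
#' @param ... Unused.
#' @method glance weight_model
#' @export
glance.weight_model <- function(x, ...) {
  tibble::tibble(panel_V = length(x$panels$V), panel_P = length(x$panels$P),
                 panel_K = length(x$panels$K),
                 panel_distinct = length(unique(unlist(x$panels))),
                 weight_form = x$weight_form, r_min = x$r_min,
                 n_train = x$n_train)
}

#' Tidy the per-group genotype weight tables
#'
#' @return For `tidy()`, a long tibble `group`, `marker`, `genotype`,
#'   `weight` (the within-group genotype frequency); for `glance()`, a
#'   one-row summary of panel sizes and settings.
#' @method tidy weight_model
#' @export
tidy.weight_model <- function(x, ...) {
  purrr::imap_dfr(x$freq, function(f, grp) {
    tibble::tibble(group = grp,
                   marker = rep(colnames(f), each = 3L),
                   genotype = rep(0:2, times = ncol(f)),
                   weight = as.vector(f))
  })
}
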