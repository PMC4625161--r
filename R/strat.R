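#' Fit a normalized-genotype principal component model
#'
#' Each genotype column is centered by its observed mean and scaled by
#' `sqrt(p(1-p))` where `p = (1 + sum g) / (2 + 2 n_valid)` is the
#' posterior allele-frequency estimate used by smartpca; missing entries
#' become zero after centering. Eigenvectors come from the sample
#' covariance `X X' / m`. Zero-variance columns are skipped and logged.
#' Eigenvector sign is fixed by making the first non-negligible entry
#' positive, so results are deterministic across linear-algebra backends.
#'
#' @param table A [geno_table()]; markers should normally be LD-pruned
#'   first ([ld_prune()]).
#' @param k Number of eigenvectors to retain (default 10).
#' @return A `pc_model`: list with `evec` (samples x k, rownames sample
#'   ids), `eval` (length k, non-increasing), `means`, `scales` and
#'   `markers` (the used markers), `loadings` (markers x k, for
#'   projection), `skipped` (zero-variance markers), `outlier_log` (empty
#'   tibble until [remove_outliers()]).
#' @export
pca_fit <- function(table, k = 10L) {
  stopifnot(inherits(table, "geno_table"))
  g <- table$genotypes
  n <- nrow(g)
  if (n < k + 1L) stop("need at least k + 1 samples", call. = FALSE)
  n_valid <- colSums(!is.na(g))
  sums <- colSums(g, na.rm = TRUE)
  means <- ifelse(n_valid > 0, sums / n_valid, 0)
  p_hat <- (1 + sums) / (2 + 2 * n_valid)
  scales <- sqrt(p_hat * (1 - p_hat))
  vr <- apply(g, 2L, stats::var, na.rm = TRUE)
  use <- !is.na(vr) & vr > 0 & scales > 0
  skipped <- table$markers$marker[!use]

  X <- sweep(g[, use, drop = FALSE], 2L, means[use], "-")
  X <- sweep(X, 2L, scales[use], "/")
  X[is.na(X)] <- 0
  m <- ncol(X)
  if (m == 0L) stop("no informative markers for PCA", call. = FALSE)
  cv <- tcrossprod(X) / m
  ee <- eigen(cv, symmetric = TRUE)
  k <- min(k, n)
  evec <- ee$vectors[, seq_len(k), drop = FALSE]
  eval <- ee$values[seq_len(k)]
  # deterministic sign: first entry of magnitude > 1e-8 made positive
  for (j in seq_len(k)) {
    nz <- which(abs(evec[, j]) > 1e-8)
    if (length(nz) && evec[nz[1L], j] < 0) evec[, j] <- -evec[, j]
  }
  rownames(evec) <- table$samples$sample
  loadings <- crossprod(X, evec)
  loadings <- sweep(loadings, 2L, pmax(m * eval, 1e-12), "/")
  structure(list(evec = evec, eval = eval,
                 means = means[use], scales = scales[use],
                 markers = table$markers$marker[use],
                 loadings = loadings, skipped = skipped,
                 samples = table$samples,
                 outlier_log = tibble::tibble(sample = character(),
                                              iteration = integer(),
                                              eigenvector = integer(),
                                              score = numeric())),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("<pc_model> %d samples, %d markers, %d eigenvectors\n",
              nrow(x$evec), length(x$markers), ncol(x$evec)))
  cat("  eigenvalues:", paste(signif(utils::head(x$eval, 5), 4),
                              collapse = ", "),
      if (length(x$eval) > 5) "...", "\n")
  if (nrow(x$outlier_log)) {
    cat(sprintf("  outliers removed: %d\n",
                length(unique(x$outlier_log$sample))))
  }
  invisible(x)
}

#' Iterative PCA outlier removal
#'
#' Repeatedly fits the PC model and removes samples whose score on any of
#' eigenvectors 1..k deviates from that eigenvector's mean by at least
#' `sigma` standard deviations, until no outliers remain or `max_iter`
#' iterations have run (the smartpca procedure; defaults sigma 6, 10
#' iterations).
#'
#' @inheritParams pca_fit
#' @param sigma Outlier threshold in SD units (default 6).
#' @param max_iter Maximum removal iterations (default 10).
#' @return A list with `table` (outliers removed) and `model` (the final
#'   `pc_model`, whose `outlier_log` records every removal with iteration,
#'   eigenvector and score).
#' @export
remove_outliers <- function(table, k = 10L, sigma = 6, max_iter = 10L) {
  stopifnot(sigma > 0, max_iter >= 1L)
  log <- tibble::tibble(sample = character(), iteration = integer(),
                        eigenvector = integer(), score = numeric())
  cur <- table
  model <- NULL
  for (it in seq_len(max_iter)) {
    if (n_samples(cur) < k + 1L) {
      stop("too few samples remain for PCA after outlier removal",
           call. = FALSE)
    }
    model <- pca_fit(cur, k = k)
    ev <- model$evec
    z <- scale(ev)
    bad <- which(abs(z) >= sigma, arr.ind = TRUE)
    if (!nrow(bad)) break
    hits <- tibble::tibble(sample = rownames(ev)[bad[, 1L]],
                           iteration = it,
                           eigenvector = as.integer(bad[, 2L]),
                           score = ev[bad])
    log <- dplyr::bind_rows(log, hits)
    keep <- setdiff(cur$samples$sample, unique(hits$sample))
    if (!length(keep)) stop("all samples flagged as outliers", call. = FALSE)
    cur <- subset_geno(cur, samples = keep)
  }
  model$outlier_log <- log
  list(table = cur, model = model)
}

#' Project samples onto a fitted PC model
#'
#' New samples are normalized with the model's per-marker means and scales
#' (missing entries to zero) and multiplied onto the model's marker
#' loadings, so training samples project onto their own coordinates.
#' Markers absent from the new table are dropped (with a warning below 90%
#' overlap); a sample missing every model marker projects to the origin
#' and is flagged.
#'
#' @param model A `pc_model` from [pca_fit()].
#' @param new_table A [geno_table()] sharing (a subset of) the model's
#'   markers.
#' @return A tibble: `sample`, `all_missing` flag, then one column per
#'   eigenvector (`EV1`, `EV2`, ...).
#' @export
project_samples <- function(model, new_table) {
  stopifnot(inherits(model, "pc_model"), inherits(new_table, "geno_table"))
  common <- intersect(model$markers, new_table$markers$marker)
  if (!length(common)) stop("no markers shared with the model", call. = FALSE)
  frac <- length(common) / length(model$markers)
  if (frac < 0.9) {
    warning(sprintf("only %.0f%% of model markers present in new table",
                    100 * frac))
  }
  mi <- match(common, model$markers)
  g <- subset_geno(new_table, markers = common)$genotypes
  X <- sweep(g, 2L, model$means[mi], "-")
  X <- sweep(X, 2L, model$scales[mi], "/")
  all_missing <- rowSums(!is.na(g)) == 0L
  X[is.na(X)] <- 0
  coords <- X %*% model$loadings[mi, , drop = FALSE]
  colnames(coords) <- paste0("EV", seq_len(ncol(coords)))
  dplyr::bind_cols(tibble::tibble(sample = new_table$samples$sample,
                                  all_missing = all_missing),
                   tibble::as_tibble(coords))
}

#' Pairwise group tests on eigenvector scores
#'
#' For each eigenvector and each pair of groups, a one-way ANOVA F-test of
#' group mean difference in scores.
#'
#' @param model A `pc_model`.
#' @param labels Group label per model sample (`NULL` uses the labels
#'   stored at fit time).
#' @return A tibble `eigenvector`, `group1`, `group2`, `p_value`.
#' @export
eigenvector_group_test <- function(model, labels = NULL) {
  stopifnot(inherits(model, "pc_model"))
  if (is.null(labels)) labels <- model$samples$group
  stopifnot(length(labels) == nrow(model$evec))
  groups <- sort(unique(labels[!is.na(labels)]))
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  pairs <- utils::combn(groups, 2L)
  purrr::map_dfr(seq_len(ncol(model$evec)), function(j) {
    purrr::map_dfr(seq_len(ncol(pairs)), function(q) {
      g1 <- pairs[1L, q]; g2 <- pairs[2L, q]
      sel <- !is.na(labels) & labels %in% c(g1, g2)
      if (min(table(labels[sel])) < 2L) {
        stop("group with fewer than 2 samples", call. = FALSE)
      }
      fit <- stats::aov(score ~ grp,
                        data = data.frame(score = model$evec[sel, j],
                                          grp = labels[sel]))
      tibble::tibble(eigenvector = j, group1 = g1, group2 = g2,
                     p_value = summary(fit)[[1L]][["Pr(>F)"]][1L])
    })
  })
}

#' EIGENSTRAT-adjusted association statistics
#'
#' Residualizes each marker's genotype vector and the binary phenotype on
#' eigenvectors 1..k (with intercept) and forms the adjusted statistic
#' `(N - k - 1) rho^2` from the correlation of residuals, referred to the
#' 1-df chi-square distribution. With `k = 0` this is the Armitage trend
#' statistic `(N - 1) rho^2` on the raw vectors. Missing genotypes are
#' mean-imputed before residualization.
#'
#' @param table A [geno_table()].
#' @param labels Logical or 0/1 phenotype per sample (cases `TRUE`).
#' @param model A `pc_model` fitted on the same samples (ignored when
#'   `k = 0`).
#' @param k Number of eigenvectors to correct on (default 10).
#' @return A tibble `marker`, `chi_adjusted`, `p_adjusted`.
#' @export
eigenstrat_adjust <- function(table, labels, model = NULL, k = 10L) {
  stopifnot(inherits(table, "geno_table"))
  y <- as.numeric(labels)
  n <- n_samples(table)
  stopifnot(length(y) == n)
  if (n <= k + 1L) stop("need N > k + 1 samples", call. = FALSE)
  if (k > 0L) {
    stopifnot(inherits(model, "pc_model"), nrow(model$evec) == n)
    E <- cbind(1, model$evec[, seq_len(k), drop = FALSE])
  } else {
    E <- matrix(1, n, 1L)
  }
  g <- table$genotypes
  cm <- colMeans(g, na.rm = TRUE)
  G <- g
  idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(idx)) G[idx] <- cm[idx[, 2L]]
  Q <- qr.Q(qr(E))
  resid <- function(v) v - Q %*% crossprod(Q, v)
  Gr <- G - Q %*% crossprod(Q, G)
  yr <- as.vector(resid(y))
  ss_g <- unname(colSums(Gr^2))
  ss_y <- sum(yr^2)
  if (ss_y < 1e-12 * n) {
    # phenotype fully explained by the eigenvectors: no testable signal
    rho <- rep(0, ncol(Gr))
  } else {
    rho <- as.vector(crossprod(Gr, yr)) / sqrt(pmax(ss_g * ss_y, 1e-300))
    rho[ss_g < 1e-12 * n] <- 0
  }
  chi <- (n - k - 1) * rho^2
  tibble::tibble(marker = table$markers$marker, chi_adjusted = chi,
                 p_adjusted = stats::pchisq(chi, 1, lower.tail = FALSE))
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi^2) / 0.4549`, the ratio of the observed median
#' 1-df chi-square statistic to its null median. Values well above 1
#' indicate uniform stratification inflation.
#'
#' @param chi_squares Numeric vector of 1-df chi-square statistics
#'   (length >= 100 recommended; `NA` dropped).
#' @return The scalar inflation factor.
#' @export
genomic_control_lambda <- function(chi_squares) {
  x <- chi_squares[!is.na(chi_squares)]
  if (length(x) < 100L) {
    warning("fewer than 100 statistics; lambda estimate is unstable")
  }
  stats::median(x) / stats::qchisq(0.5, df = 1)
}
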