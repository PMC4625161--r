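#' 2x2 allele count table for a case/control comparison
#'
#' Counts minor and major alleles over the non-missing genotypes of each
#' arm. Minor-allele polarity is the table's cohort-wide polarity.
#'
#' @param table A [geno_table()].
#' @param marker Marker id.
#' @param case_ids,control_ids Disjoint, non-empty sample id sets.
#' @return A named numeric vector `c(case_minor, case_major, control_minor,
#'   control_major)`; all `NA` (with attribute `undefined = TRUE`) when the
#'   marker is entirely missing in either arm.
#' @export
allelic_table <- function(table, marker, case_ids, control_ids) {
  stopifnot(length(case_ids) > 0L, length(control_ids) > 0L)
  if (length(intersect(case_ids, control_ids))) {
    stop("case and control sets overlap", call. = FALSE)
  }
  g <- subset_geno(table, markers = marker)$genotypes[, 1L]
  arm <- function(ids) {
    x <- g[ids]
    x <- x[!is.na(x)]
    c(minor = sum(x), major = 2L * length(x) - sum(x))
  }
  ca <- arm(case_ids); co <- arm(control_ids)
  out <- c(case_minor = ca[["minor"]], case_major = ca[["major"]],
           control_minor = co[["minor"]], control_major = co[["major"]])
  if (sum(ca) == 0L || sum(co) == 0L) {
    out[] <- NA_real_
    attr(out, "undefined") <- TRUE
  }
  out
}

#' Allelic chi-square test on a 2x2 allele table
#'
#' Pearson chi-square without continuity correction,
#' `n (ad - bc)^2 / (r1 r2 c1 c2)`, with the p-value from the 1-df
#' chi-square distribution. A zero margin makes the statistic undefined.
#'
#' @param counts Numeric vector `c(case_minor, case_major, control_minor,
#'   control_major)` as returned by [allelic_table()].
#' @return A list with `chi_square` and `p_theoretical` (both `NA` for a
#'   zero margin).
#' @examples
#' allelic_chi2(c(11, 149, 0, 250))
#' @export
allelic_chi2 <- function(counts) {
  counts <- as.numeric(counts)   # margin products overflow integers
  a <- counts[[1L]]; b <- counts[[2L]]; c_ <- counts[[3L]]; d <- counts[[4L]]
  if (anyNA(counts)) return(list(chi_square = NA_real_, p_theoretical = NA_real_))
  n <- a + b + c_ + d
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  if (den == 0) return(list(chi_square = NA_real_, p_theoretical = NA_real_))
  chi <- n * (a * d - b * c_)^2 / den
  list(chi_square = chi,
       p_theoretical = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Allelic odds ratio
#'
#' `(case_minor x control_major) / (case_major x control_minor)`;
#' undefined (`NA`) when any cell is zero, matching how published tables
#' print `NA` against a still-defined chi-square.
#'
#' @inheritParams allelic_chi2
#' @return A single numeric odds ratio or `NA`.
#' @export
odds_ratio <- function(counts) {
  if (anyNA(counts) || any(counts == 0)) return(NA_real_)
  (counts[[1L]] * counts[[4L]]) / (counts[[2L]] * counts[[3L]])
}

# chi-square for many permuted case assignments of one marker.
# x: dosage vector (NA ok); case_mat: logical n x B matrix of case labels.
perm_chi2 <- function(x, case_mat) {
  ok <- !is.na(x)
  x <- x[ok]
  cm <- case_mat[ok, , drop = FALSE]
  a <- as.vector(crossprod(cm, x))               # case minor
  ncase <- colSums(cm)
  b <- 2 * ncase - a
  tot_minor <- sum(x)
  c_ <- tot_minor - a
  d <- 2 * (length(x) - ncase) - c_
  n <- a + b + c_ + d
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi <- ifelse(den == 0, 0, n * (a * d - b * c_)^2 / den)
  chi
}

#' Adaptive permutation empirical p-value for one marker
#'
#' Case/control labels are permuted and the allelic chi-square recomputed;
#' the empirical p-value is `(R + 1) / (N + 1)` with `R` the number of
#' permutations at least as extreme as the observed statistic. A marker is
#' dropped early (fewer than `max_perms` permutations) once the lower bound
#' of a `100(1 - beta)%` normal-approximation binomial confidence interval
#' on the empirical p exceeds `alpha_stop`; checks happen at batch ends,
#' with batch sizes growing geometrically. Survivors run to `max_perms`.
#'
#' When the number of distinct case assignments `choose(n, n_case)` does
#' not exceed `max_perms`, the null is enumerated exhaustively instead: the
#' returned p is then the exact permutation p `R / N` over all `N` distinct
#' assignments (the observed assignment included), and the marker counts as
#' complete.
#'
#' @param table A [geno_table()].
#' @param marker Marker id.
#' @param case_ids,control_ids Sample id sets defining the comparison.
#' @param max_perms Permutation budget (default 1e6).
#' @param seed Integer seed.
#' @param alpha_stop Significance ceiling for early dropping (default 0).
#' @param beta Confidence-interval tail mass for the drop rule
#'   (default 1e-4).
#' @param batch_init,batch_growth First batch size and geometric growth
#'   factor.
#' @return A tibble with `p_empirical` (the tie-inclusive `(R+1)/(N+1)`
#'   estimator used for reporting and filtering), `p_mid` (the mid-p
#'   estimator counting ties at the observed statistic with weight 1/2 --
#'   the appropriate quantity when comparing against the continuous
#'   chi-square p, whose discrete point mass at the observed allele count
#'   otherwise biases the comparison), `permutations_achieved`,
#'   `exceedances`, `completed` (ran to `max_perms` or enumerated
#'   exhaustively) and `exhaustive`.
#' @export
adaptive_permutation <- function(table, marker, case_ids, control_ids,
                                 max_perms = 1e6, seed = 1L,
                                 alpha_stop = 0, beta = 1e-4,
                                 batch_init = 50L, batch_growth = 1.5) {
  ids <- c(case_ids, control_ids)
  g <- subset_geno(table, samples = ids, markers = marker)$genotypes[, 1L]
  n <- length(ids)
  n_case <- length(case_ids)
  is_case <- c(rep(TRUE, n_case), rep(FALSE, length(control_ids)))

  obs <- allelic_chi2(allelic_table(table, marker, case_ids, control_ids))
  if (is.na(obs$chi_square) || stats::var(g, na.rm = TRUE) %in% c(0, NA)) {
    return(tibble::tibble(marker = marker, p_empirical = 1, p_mid = 1,
                          permutations_achieved = as.integer(batch_init),
                          exceedances = as.integer(batch_init),
                          completed = FALSE, exhaustive = FALSE))
  }
  tol <- 1e-9 * max(1, obs$chi_square)
  chi_lo <- obs$chi_square - tol
  chi_hi <- obs$chi_square + tol
  out <- function(R, R_gt, done, completed, exhaustive) {
    pe <- if (exhaustive) R / done else (R + 1) / (done + 1)
    tibble::tibble(marker = marker, p_empirical = pe,
                   p_mid = (R_gt + 0.5 * (R - R_gt)) / done,
                   permutations_achieved = as.integer(done),
                   exceedances = as.integer(R),
                   completed = completed, exhaustive = exhaustive)
  }

  n_distinct <- suppressWarnings(choose(n, n_case))
  if (is.finite(n_distinct) && n_distinct <= max_perms) {
    combs <- utils::combn(n, n_case)
    case_mat <- matrix(FALSE, n, ncol(combs))
    case_mat[cbind(as.vector(combs), rep(seq_len(ncol(combs)),
                                         each = n_case))] <- TRUE
    chi <- perm_chi2(g, case_mat)
    return(out(sum(chi >= chi_lo), sum(chi > chi_hi), ncol(combs),
               completed = TRUE, exhaustive = TRUE))
  }

  set.seed(seed)
  z <- stats::qnorm(1 - beta / 2)
  done <- 0L; R <- 0L; R_gt <- 0L
  batch <- as.integer(batch_init)
  repeat {
    b <- min(batch, max_perms - done)
    case_mat <- matrix(FALSE, n, b)
    for (k in seq_len(b)) case_mat[sample.int(n, n_case), k] <- TRUE
    chi <- perm_chi2(g, case_mat)
    R <- R + sum(chi >= chi_lo)
    R_gt <- R_gt + sum(chi > chi_hi)
    done <- done + b
    pe <- (R + 1) / (done + 1)
    if (done >= max_perms) {
      return(out(R, R_gt, done, completed = TRUE, exhaustive = FALSE))
    }
    lower <- pe - z * sqrt(pe * (1 - pe) / done)
    if (lower > alpha_stop) {
      return(out(R, R_gt, done, completed = FALSE, exhaustive = FALSE))
    }
    batch <- as.integer(ceiling(batch * batch_growth))
  }
}

#' One-vs-rest allelic association scan
#'
#' Runs the allelic chi-square test for every marker in each of the three
#' one-vs-rest comparisons (`V_vs_PK`, `P_vs_VK`, `K_vs_VP`), optionally
#' applying the per-comparison Hardy-Weinberg control filter first and the
#' adaptive permutation stage to markers at or below `perm_p_max`.
#'
#' @param table A [geno_table()] whose samples carry group labels V/P/K.
#' @param comparisons Character subset of the three comparison names.
#' @param hwe_alpha If non-`NULL`, markers failing [hwe_filter_in_controls()]
#'   at this level (controls of each comparison) are excluded from that
#'   comparison.
#' @param max_perms,perm_p_max Permutation budget, and the theoretical-p
#'   screen above which markers are not permuted (their `completed` flag is
#'   `FALSE`). `perm_p_max = 0` disables permutation entirely.
#' @param seed Integer seed for the permutation stage.
#' @return A tibble of association records: one row per (marker,
#'   comparison) with group frequencies, counts, `chi_square`,
#'   `p_theoretical`, `odds_ratio`, and (where permuted) `p_empirical`,
#'   `permutations_achieved`, `completed`.
#' @export
assoc_scan <- function(table, comparisons = names(comparison_groups()),
                       hwe_alpha = NULL, max_perms = 1e6,
                       perm_p_max = 0, seed = 1L) {
  comps <- comparison_groups()[comparisons]
  stopifnot(length(comps) > 0L)
  purrr::imap_dfr(comps, function(cmp, cmp_name) {
    case_ids <- group_samples(table, cmp$case)
    control_ids <- group_samples(table, cmp$control)
    if (!length(case_ids) || !length(control_ids)) {
      stop("comparison ", cmp_name, " has an empty arm", call. = FALSE)
    }
    tab <- table
    if (!is.null(hwe_alpha)) {
      tab <- hwe_filter_in_controls(tab, control_ids, alpha = hwe_alpha)$table
    }
    g <- subset_geno(tab, samples = c(case_ids, control_ids))$genotypes
    nc <- length(case_ids)
    ca <- g[seq_len(nc), , drop = FALSE]
    co <- g[-seq_len(nc), , drop = FALSE]
    a <- colSums(ca, na.rm = TRUE)
    b <- 2 * colSums(!is.na(ca)) - a
    c_ <- colSums(co, na.rm = TRUE)
    d <- 2 * colSums(!is.na(co)) - c_
    n <- a + b + c_ + d
    den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
    chi <- ifelse(den == 0, NA_real_, n * (a * d - b * c_)^2 / den)
    res <- tibble::tibble(
      marker = tab$markers$marker, comparison = cmp_name,
      case_minor = a, case_major = b, control_minor = c_, control_major = d,
      maf_case = ifelse(a + b > 0, a / (a + b), NA_real_),
      maf_control = ifelse(c_ + d > 0, c_ / (c_ + d), NA_real_),
      chi_square = chi,
      p_theoretical = stats::pchisq(chi, 1, lower.tail = FALSE),
      odds_ratio = ifelse(a > 0 & b > 0 & c_ > 0 & d > 0,
                          a * d / (b * c_), NA_real_),
      p_empirical = NA_real_, permutations_achieved = NA_integer_,
      completed = FALSE)
    if (perm_p_max > 0) {
      todo <- which(!is.na(res$p_theoretical) &
                      res$p_theoretical <= perm_p_max)
      for (jj in seq_along(todo)) {
        j <- todo[jj]
        pr <- adaptive_permutation(tab, res$marker[j], case_ids, control_ids,
                                   max_perms = max_perms,
                                   seed = seed + 31L * jj)
        res$p_empirical[j] <- pr$p_empirical
        res$permutations_achieved[j] <- as.integer(pr$permutations_achieved)
        res$completed[j] <- pr$completed
      }
    }
    res
  })
}

#' The true-positive filter: survivors of full permutation at low p
#'
#' Keeps association records whose theoretical p-value is at or below
#' `p_ceiling` and whose permutation stage ran to completion (all
#' `max_perms` permutations, or exhaustive enumeration). The marker panel
#' is the set of distinct marker ids across comparisons: a marker may enter
#' through two comparisons.
#'
#' @param records Association records (from [assoc_scan()], or a published
#'   summary table carrying `p_theoretical` plus either a `completed` flag
#'   or `n_permutations`).
#' @param p_ceiling Theoretical p ceiling (default 1e-5).
#' @param max_perms Required permutation count when `records` carries
#'   `n_permutations` instead of `completed` (default 1e6).
#' @return A list with `records` (passing rows) and `panel` (distinct
#'   marker ids).
#' @export
true_positive_filter <- function(records, p_ceiling = 1e-5, max_perms = 1e6) {
  id_col <- if ("marker" %in% names(records)) "marker" else "rsid"
  completed <- if ("completed" %in% names(records)) {
    records$completed
  } else if ("n_permutations" %in% names(records)) {
    records$n_permutations >= max_perms
  } else {
    stop("records need a 'completed' or 'n_permutations' column",
         call. = FALSE)
  }
  keep <- !is.na(records$p_theoretical) &
    records$p_theoretical <= p_ceiling & completed
  passing <- records[keep, , drop = FALSE]
  list(records = passing, panel = unique(passing[[id_col]]))
}
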