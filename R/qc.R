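#' Remove samples with low genotype call rate
#'
#' @param table A [geno_table()].
#' @param threshold Minimum fraction of non-missing genotypes a sample must
#'   have to be retained (default 0.95). Must lie in (0, 1].
#' @return A list with `table` (samples passing) and `report` (tibble
#'   `sample`, `call_rate`, `removed`, `reason`).
#' @export
sample_call_rate_filter <- function(table, threshold = 0.95) {
  stopifnot(inherits(table, "geno_table"), n_samples(table) > 0L)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  cr <- sample_call_rate(table)
  removed <- cr$call_rate < threshold
  report <- dplyr::mutate(
    cr, removed = removed,
    reason = ifelse(removed, "low_call_rate", NA_character_))
  keep <- cr$sample[!removed]
  if (!length(keep)) stop("all samples fail the call-rate filter", call. = FALSE)
  list(table = subset_geno(table, samples = keep), report = report)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test on genotype counts: given the allele counts, the
#' p-value is the summed probability of every heterozygote count whose
#' conditional probability does not exceed that of the observed count
#' (the convention of PLINK's exact HWE test). Monomorphic markers return
#' p = 1 by convention.
#'
#' @param n_hom1,n_het,n_hom2 Genotype counts (either homozygote may be the
#'   minor one; the test is symmetric). Vectors recycle.
#' @return Numeric vector of exact p-values in (0, 1].
#' @examples
#' hwe_exact_p(25, 50, 25)     # modal configuration: p = 1
#' hwe_exact_p(0, 100, 0)      # extreme heterozygote excess
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  nn <- cbind(n_hom1, n_het, n_hom2)
  if (any(nn < 0) || any(rowSums(nn) < 1)) {
    stop("counts must be non-negative with total >= 1", call. = FALSE)
  }
  apply(nn, 1L, function(x) hwe_exact_p_scalar(x[1L], x[2L], x[3L]))
}

hwe_exact_p_scalar <- function(n_hom1, n_het, n_hom2) {
  N <- n_hom1 + n_het + n_hom2
  rare <- 2L * min(n_hom1, n_hom2) + n_het
  if (rare == 0L) return(1)
  # heterozygote counts share the parity of the rare-allele count
  h <- seq(rare %% 2L, rare, by = 2L)
  h <- h[(rare - h) / 2 + (2L * N - rare - h) / 2 >= 0 & h <= 2L * N - rare]
  logp <- lgamma(N + 1) - lgamma((rare - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((2 * N - rare - h) / 2 + 1) + h * log(2) +
    lgamma(rare + 1) + lgamma(2 * N - rare + 1) - lgamma(2 * N + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[h == n_het]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-10)]))
}

# genotype counts (hom-major, het, hom-minor) per marker over a sample set
genotype_counts <- function(table, samples = NULL) {
  gt <- if (is.null(samples)) table else subset_geno(table, samples = samples)
  g <- gt$genotypes
  tibble::tibble(marker = gt$markers$marker,
                 n_hom_major = colSums(g == 0L, na.rm = TRUE),
                 n_het = colSums(g == 1L, na.rm = TRUE),
                 n_hom_minor = colSums(g == 2L, na.rm = TRUE))
}

#' Filter markers out of Hardy-Weinberg equilibrium in controls
#'
#' The exact HWE p-value is computed on the designated control samples
#' only; markers with p below `alpha` are removed. In the one-vs-rest
#' design, controls differ per comparison, so this filter is applied once
#' per comparison and the resulting marker sets are kept separate.
#'
#' @param table A [geno_table()].
#' @param control_samples Sample ids forming the control arm.
#' @param alpha Removal threshold on the exact p-value (default 0.001).
#' @return A list with `table` (markers passing) and `report` (tibble
#'   `marker`, `p_hwe`, `removed`, `reason`).
#' @export
hwe_filter_in_controls <- function(table, control_samples, alpha = 0.001) {
  stopifnot(inherits(table, "geno_table"))
  if (!length(control_samples)) stop("control set is empty", call. = FALSE)
  cnt <- genotype_counts(table, control_samples)
  called <- cnt$n_hom_major + cnt$n_het + cnt$n_hom_minor
  p <- rep(1, nrow(cnt))
  ok <- called >= 1
  p[ok] <- hwe_exact_p(cnt$n_hom_major[ok], cnt$n_het[ok], cnt$n_hom_minor[ok])
  removed <- p < alpha
  report <- tibble::tibble(marker = cnt$marker, p_hwe = p, removed = removed,
                           reason = ifelse(removed, "hwe_controls",
                                           NA_character_))
  list(table = subset_geno(table, markers = cnt$marker[!removed]),
       report = report)
}

#' Prune markers in strong linkage disequilibrium
#'
#' Greedy windowed scan in marker order: within each sliding window, for
#' any pair of still-kept markers whose squared genotype-dosage correlation
#' exceeds `r2_threshold`, the later marker is dropped. Deterministic.
#' Zero-variance markers carry no correlation signal and are kept, except
#' that exact duplicate columns (including constant duplicates) are treated
#' as r-squared 1.
#'
#' @param table A [geno_table()].
#' @param r2_threshold Squared-correlation threshold (default 0.75).
#' @param window Window width in markers (default 50).
#' @param step Window slide in markers (default 5).
#' @return A list with `kept` (marker ids retained, in order), `table`
#'   (the pruned [geno_table()]) and `report` (tibble of dropped markers
#'   with the partner and r-squared that triggered the drop).
#' @export
ld_prune <- function(table, r2_threshold = 0.75, window = 50L, step = 5L) {
  stopifnot(inherits(table, "geno_table"), n_markers(table) >= 1L,
            r2_threshold > 0, window >= 2L, step >= 1L)
  g <- table$genotypes
  m <- ncol(g)
  keep <- rep(TRUE, m)
  drops <- list()
  starts <- unique(c(seq(1L, max(1L, m - 1L), by = step)))
  for (s in starts) {
    idx <- s:min(s + window - 1L, m)
    idx <- idx[keep[idx]]
    if (length(idx) < 2L) next
    sub <- g[, idx, drop = FALSE]
    r <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    r2 <- r^2
    for (a in seq_len(length(idx) - 1L)) {
      if (!keep[idx[a]]) next
      for (b in (a + 1L):length(idx)) {
        if (!keep[idx[b]]) next
        v <- r2[a, b]
        if (is.na(v)) {
          # undefined correlation: only exact duplicates count
          v <- if (identical(sub[, a], sub[, b])) 1 else 0
        }
        if (v > r2_threshold - 1e-12) {
          keep[idx[b]] <- FALSE
          drops[[length(drops) + 1L]] <- tibble::tibble(
            marker = table$markers$marker[idx[b]],
            partner = table$markers$marker[idx[a]], r2 = v)
        }
      }
    }
  }
  kept <- table$markers$marker[keep]
  report <- if (length(drops)) dplyr::bind_rows(drops) else
    tibble::tibble(marker = character(), partner = character(),
                   r2 = numeric())
  list(kept = kept, table = subset_geno(table, markers = kept),
       report = report)
}

# TRUE where the child dosage is impossible given the two parent dosages
mendel_inconsistent <- function(fa, mo, ch) {
  # a parent with dosage 2 must transmit a minor allele, dosage 0 a major
  # allele, dosage 1 either; the child dosage must fall in [minc, maxc]
  minc <- (fa == 2L) + (mo == 2L)
  maxc <- (fa >= 1L) + (mo >= 1L)
  ch < minc | ch > maxc
}

#' Mendelian inconsistency rate per trio
#'
#' A child genotype is inconsistent when it cannot arise from one allele of
#' each parent (e.g. parents both homozygous major cannot have a
#' heterozygous child). Markers with a missing genotype in any trio member
#' are skipped.
#'
#' @param table A [geno_table()] containing all trio members.
#' @param pedigree Tibble with columns `child`, `father`, `mother`.
#' @return A tibble `child`, `n_tested`, `n_inconsistent`, `rate`.
#' @export
mendel_check <- function(table, pedigree) {
  stopifnot(inherits(table, "geno_table"),
            all(c("child", "father", "mother") %in% names(pedigree)))
  ids <- table$samples$sample
  miss <- setdiff(unlist(pedigree[c("father", "mother", "child")]), ids)
  if (length(miss)) {
    stop("pedigree member(s) absent from table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  g <- table$genotypes
  purrr::pmap_dfr(pedigree, function(child, father, mother, ...) {
    fa <- g[father, ]; mo <- g[mother, ]; ch <- g[child, ]
    ok <- !is.na(fa) & !is.na(mo) & !is.na(ch)
    bad <- mendel_inconsistent(fa[ok], mo[ok], ch[ok])
    tibble::tibble(child = child, n_tested = sum(ok),
                   n_inconsistent = sum(bad),
                   rate = ifelse(sum(ok) > 0, mean(bad), NA_real_))
  })
}

#' Modal-genotype imputer
#'
#' Reference imputation engine for [mask_and_concordance()]: fills each
#' missing genotype with the most frequent genotype of that marker (ties to
#' the lower dosage).
#'
#' @param table A [geno_table()] with missing entries.
#' @return A completed [geno_table()].
#' @export
impute_mode <- function(table) {
  g <- table$genotypes
  for (j in seq_len(ncol(g))) {
    hole <- is.na(g[, j])
    if (!any(hole)) next
    cnt <- tabulate(g[!hole, j] + 1L, 3L)
    g[hole, j] <- if (all(cnt == 0L)) 0L else which.max(cnt) - 1L
  }
  geno_table(g, table$markers, table$samples)
}

#' Masking/concordance harness for imputation engines
#'
#' Repeatedly masks a random fraction of the non-missing genotypes, runs a
#' user-supplied imputer (a function `geno_table -> geno_table` that must
#' leave no holes at the masked positions), and scores the fraction of
#' masked entries recovered exactly. Replicates default to 110.
#'
#' @param table A [geno_table()].
#' @param mask_fraction Fraction of non-missing entries to mask, in (0, 1).
#' @param imputer Imputation callable; default [impute_mode()].
#' @param n_reps Number of mask/impute replicates (default 110).
#' @param seed Integer seed.
#' @return A tibble with `mask_fraction`, `n_reps`, `mean_concordance`,
#'   `sd_concordance` and a list-column `concordance` of per-replicate
#'   values.
#' @export
mask_and_concordance <- function(table, mask_fraction, imputer = impute_mode,
                                 n_reps = 110L, seed = 1L) {
  stopifnot(inherits(table, "geno_table"),
            mask_fraction > 0, mask_fraction < 1, n_reps >= 1L)
  set.seed(seed)
  g0 <- table$genotypes
  observed <- which(!is.na(g0))
  n_mask <- max(1L, round(mask_fraction * length(observed)))
  conc <- purrr::map_dbl(seq_len(n_reps), function(rep) {
    idx <- sample(observed, n_mask)
    g <- g0
    g[idx] <- NA_integer_
    filled <- imputer(geno_table(g, table$markers, table$samples))
    gi <- filled$genotypes
    if (anyNA(gi[idx])) {
      stop("imputer contract violation: masked entries left missing",
           call. = FALSE)
    }
    mean(gi[idx] == g0[idx])
  })
  tibble::tibble(mask_fraction = mask_fraction, n_reps = n_reps,
                 mean_concordance = mean(conc), sd_concordance = stats::sd(conc),
                 concordance = list(conc))
}
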