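#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study cohort the package is designed around: three
#' constitutional-type groups of 80/60/65 samples drawn from two ancestral
#' backgrounds (Balding-Nichols differentiation), a small minority of
#' markers carrying group-specific allele-frequency shifts of the magnitude
#' seen in the published association panel (case-control gaps around 0.2),
#' and a missing-genotype rate matching the reported array call rate
#' (1 - 0.966).
#'
#' @param n_per_group Integer vector of length 3: samples in groups V, P, K.
#' @param n_markers Number of markers to simulate.
#' @param frac_associated Fraction of markers given a planted group effect.
#' @param effect_delta Allele-frequency shift added for the affected group
#'   (post-shift frequencies are clipped to `[0.01, 0.99]`).
#' @param fst Balding-Nichols differentiation between the two ancestries
#'   (`0 <= fst < 1`; 0 means a single panmictic background).
#' @param admix_frac Fraction of samples drawn from ancestry 2.
#' @param missing_rate Fraction of genotype calls masked to missing.
#' @param seed Integer seed; every draw flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_group = c(80L, 60L, 65L), n_markers = 1000L,
                       frac_associated = 0.01, effect_delta = 0.2,
                       fst = 0.05, admix_frac = 0.5,
                       missing_rate = 0.034, seed = 1L) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_markers = as.integer(n_markers),
              frac_associated = frac_associated, effect_delta = effect_delta,
              fst = fst, admix_frac = admix_frac,
              missing_rate = missing_rate, seed = as.integer(seed))
  stopifnot(length(cfg$n_per_group) == 3L, all(cfg$n_per_group >= 0L),
            cfg$n_markers >= 1L,
            cfg$frac_associated >= 0, cfg$frac_associated <= 1,
            cfg$fst >= 0, cfg$fst < 1,
            cfg$admix_frac >= 0, cfg$admix_frac <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1)
  if (cfg$effect_delta < 0 || cfg$effect_delta > 0.9) {
    stop("effect_delta must be in [0, 0.9]: larger shifts cannot be ",
         "accommodated within the clipped frequency range", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a structured three-group cohort
#'
#' Marker ancestral frequencies are drawn Uniform(0.05, 0.95); each of the
#' two ancestries then gets a Balding-Nichols frequency
#' `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)`. For planted markers, the affected
#' group's frequency is shifted by `effect_delta` (clipped to
#' `[0.01, 0.99]`); group effects are planted independently of ancestry.
#' Genotypes are drawn `Binomial(2, p)` (Hardy-Weinberg within each
#' ancestry-by-group stratum) and masked at `missing_rate`. The whole draw
#' is reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{table}{the simulated [geno_table()];}
#'     \item{truth}{a list with `markers` (per-marker tibble: ancestral and
#'       per-ancestry frequencies, affected group, planted delta),
#'       `samples` (per-sample tibble: group, ancestry) and the `config`.}
#'   }
#' @examples
#' sim <- simulate_cohort(sim_config(n_markers = 50, seed = 42))
#' sim$table
#' dplyr::count(sim$truth$markers, affected_group)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- sum(config$n_per_group)
  m <- config$n_markers
  groups <- rep(c("V", "P", "K"), times = config$n_per_group)

  p0 <- stats::runif(m, 0.05, 0.95)
  if (config$fst > 0) {
    F <- config$fst
    a <- p0 * (1 - F) / F
    b <- (1 - p0) * (1 - F) / F
    p_anc <- cbind(stats::rbeta(m, a, b), stats::rbeta(m, a, b))
  } else {
    p_anc <- cbind(p0, p0)
  }
  p_anc <- pmin(pmax(p_anc, 0.01), 0.99)

  n_planted <- round(config$frac_associated * m)
  planted <- if (n_planted > 0) sample.int(m, n_planted) else integer()
  affected <- rep(NA_character_, m)
  delta <- rep(0, m)
  if (n_planted > 0) {
    affected[planted] <- sample(c("V", "P", "K"), n_planted, replace = TRUE)
    # push the frequency toward whichever bound has room, so the planted
    # contrast survives clipping
    sgn <- ifelse(p_anc[planted, 1L] <= 0.5, 1, -1)
    delta[planted] <- sgn * config$effect_delta
  }

  ancestry <- stats::rbinom(n, 1L, config$admix_frac) + 1L
  P <- matrix(p_anc[, 1L], n, m, byrow = TRUE)
  P[ancestry == 2L, ] <- matrix(p_anc[, 2L], sum(ancestry == 2L), m,
                                byrow = TRUE)
  if (n_planted > 0) {
    for (j in planted) {
      hit <- groups == affected[j]
      P[hit, j] <- pmin(pmax(P[hit, j] + delta[j], 0.01), 0.99)
    }
  }

  g <- matrix(stats::rbinom(n * m, 2L, as.vector(P)), n, m)
  if (config$missing_rate > 0) {
    g[stats::runif(n * m) < config$missing_rate] <- NA_integer_
  }

  # code dosages against the realized cohort minor allele (alleles "A" and
  # "G" per marker; ties at 0.5 go to the alphabetically later allele)
  f1 <- colSums(g, na.rm = TRUE) / (2 * pmax(colSums(!is.na(g)), 1L))
  flip <- f1 >= 0.5
  g[, flip] <- 2L - g[, flip]
  allele_pairs <- cbind(ifelse(flip, "G", "A"), ifelse(flip, "A", "G"))
  table <- geno_table(
    g,
    markers = tibble::tibble(marker = sprintf("sim%05d", seq_len(m)),
                             chr = "1",
                             pos = as.integer(seq_len(m) * 1000L),
                             allele_minor = allele_pairs[, 1L],
                             allele_major = allele_pairs[, 2L]),
    samples = tibble::tibble(sample = sprintf("S%03d", seq_len(n)),
                             group = groups))
  truth <- list(
    markers = tibble::tibble(marker = table$markers$marker,
                             p_ancestral = p0,
                             p_anc1 = p_anc[, 1L], p_anc2 = p_anc[, 2L],
                             affected_group = affected, delta = delta,
                             coded_allele = allele_pairs[, 1L]),
    samples = tibble::tibble(sample = table$samples$sample,
                             group = groups, ancestry = ancestry),
    config = config)
  list(table = table, truth = truth)
}

#' Simulate parent-parent-child trios
#'
#' Parents are drawn in Hardy-Weinberg proportions at frequencies
#' Uniform(0.05, 0.95); each child allele is transmitted from the matching
#' parent. Genotyping error is injected by replacing the child genotype, at
#' a fraction `error_rate` of markers, with a uniform draw from \{0, 1, 2\}
#' (which may coincide with the true genotype, so only a subset of injected
#' errors is detectable as a Mendelian inconsistency).
#'
#' @param n_trios Number of trios (>= 1).
#' @param n_markers Markers per trio table.
#' @param error_rate Fraction of child genotypes re-randomized.
#' @param seed Integer seed.
#' @return A list with `table` (a [geno_table()] holding father, mother and
#'   child of each trio) and `pedigree` (tibble `child`, `father`,
#'   `mother`).
#' @seealso [mendel_check()]
#' @export
simulate_trios <- function(n_trios, n_markers, error_rate = 0, seed = 1L) {
  stopifnot(n_trios >= 1L, n_markers >= 1L,
            error_rate >= 0, error_rate <= 1)
  set.seed(seed)
  m <- n_markers
  p <- stats::runif(m, 0.05, 0.95)
  ids <- function(role) sprintf("trio%03d_%s", seq_len(n_trios), role)
  fa <- matrix(stats::rbinom(n_trios * m, 2L, rep(p, each = n_trios)),
               n_trios, m)
  mo <- matrix(stats::rbinom(n_trios * m, 2L, rep(p, each = n_trios)),
               n_trios, m)
  transmit <- function(par) {
    matrix(stats::rbinom(length(par), 1L, as.vector(par) / 2),
           nrow(par), ncol(par))
  }
  ch <- transmit(fa) + transmit(mo)
  if (error_rate > 0) {
    err <- stats::runif(n_trios * m) < error_rate
    ch[err] <- sample(0:2, sum(err), replace = TRUE)
  }
  g <- rbind(fa, mo, ch)
  rownames(g) <- c(ids("father"), ids("mother"), ids("child"))
  table <- geno_table(
    g,
    markers = tibble::tibble(marker = sprintf("trm%05d", seq_len(m)),
                             chr = "1", pos = as.integer(seq_len(m) * 500L),
                             allele_minor = "A", allele_major = "G"),
    samples = tibble::tibble(sample = rownames(g), group = NA_character_))
  list(table = table,
       pedigree = tibble::tibble(child = ids("child"), father = ids("father"),
                                 mother = ids("mother")))
}
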