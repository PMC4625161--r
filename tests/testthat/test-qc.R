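test_that("call-rate filter removes samples below threshold", {
  g <- rbind(c(0L, 1L, NA, NA, NA, NA, 2L, 0L, 1L, 0L),   # 60% called
             matrix(1L, 3, 10))
  gt <- geno_table(g,
                   markers = tibble::tibble(marker = sprintf("m%d", 1:10),
                                            chr = "1", pos = 1:10 * 10L,
                                            allele_minor = "A",
                                            allele_major = "G"),
                   samples = tibble::tibble(sample = paste0("s", 1:4),
                                            group = NA_character_))
  out <- sample_call_rate_filter(gt, threshold = 0.95)
  expect_equal(out$report$reason[1], "low_call_rate")
  expect_equal(n_samples(out$table), 3L)

  # complete table: nothing removed
  full <- sample_call_rate_filter(subset_geno(gt, samples = paste0("s", 2:4)))
  expect_equal(sum(full$report$removed), 0L)

  expect_error(sample_call_rate_filter(gt, threshold = 0), "threshold")
})

test_that("call-rate removal fraction matches the binomial tail", {
  # missing_rate 0.06 at threshold 0.95: removal prob = P(Bin(m, 0.94) < 0.95 m)
  m <- 200L
  p_remove <- stats::pbinom(ceiling(0.95 * m) - 1, m, 0.94)
  removed <- 0L; total <- 0L
  for (seed in 1:8) {
    sim <- simulate_cohort(sim_config(n_per_group = c(40L, 30L, 30L),
                                      n_markers = m, missing_rate = 0.06,
                                      frac_associated = 0, seed = 300L + seed))
    rep <- sample_call_rate_filter(sim$table)$report
    removed <- removed + sum(rep$removed)
    total <- total + nrow(rep)
  }
  se <- sqrt(p_remove * (1 - p_remove) / total)
  expect_lt(abs(removed / total - p_remove), 3 * se)
})

test_that("exact HWE test matches its enumeration oracle", {
  expect_equal(hwe_exact_p(25, 50, 25), 1.0)
  expect_equal(hwe_exact_p(0, 100, 0), oracle_hwe_p(0, 100, 0),
               tolerance = 1e-12)
  expect_lt(hwe_exact_p(0, 100, 0), 1e-20)
  expect_gte(hwe_exact_p(4, 32, 64), 0.99)    # perfect proportions, p = 0.2
  expect_equal(hwe_exact_p(10, 0, 0), 1)      # monomorphic convention
  expect_error(hwe_exact_p(-1, 2, 3), "non-negative")

  # spot sweep here; the exhaustive total <= 50 sweep runs in acceptance
  cases <- expand.grid(a = c(0, 1, 3, 8), h = c(0, 2, 5, 11),
                       b = c(0, 1, 4, 9))
  cases <- cases[rowSums(cases) >= 1, ]
  for (i in seq_len(nrow(cases))) {
    expect_equal(hwe_exact_p(cases$a[i], cases$h[i], cases$b[i]),
                 oracle_hwe_p(cases$a[i], cases$h[i], cases$b[i]),
                 tolerance = 1e-12,
                 info = paste(cases[i, ], collapse = "/"))
  }
})

test_that("HWE control filter removes disequilibrium markers per comparison", {
  n <- 60L
  g <- cbind(rep(1L, n),                       # all-het: extreme HWE failure
             rep(c(0L, 1L, 2L), n / 3),        # near-perfect proportions
             rep(0L, n))                       # monomorphic: kept (p = 1)
  gt <- geno_table(g,
                   markers = tibble::tibble(marker = c("bad", "good", "mono"),
                                            chr = "1", pos = c(1L, 2L, 3L),
                                            allele_minor = "A",
                                            allele_major = "G"),
                   samples = tibble::tibble(sample = sprintf("s%02d", 1:n),
                                            group = rep(c("P", "K"), n / 2)))
  out <- hwe_filter_in_controls(gt, group_samples(gt, c("P", "K")))
  expect_equal(out$report$marker[out$report$removed], "bad")
  expect_setequal(out$table$markers$marker, c("good", "mono"))
  expect_error(hwe_filter_in_controls(gt, character(0)), "empty")
})

test_that("null-cohort HWE removal stays at or below alpha", {
  removed <- 0L; total <- 0L
  for (seed in 1:10) {
    sim <- simulate_cohort(sim_config(n_markers = 400L, fst = 0,
                                      frac_associated = 0, missing_rate = 0,
                                      seed = 40L + seed))
    ctrl <- group_samples(sim$table, c("P", "K"))
    rep <- hwe_filter_in_controls(sim$table, ctrl)$report
    removed <- removed + sum(rep$removed)
    total <- total + nrow(rep)
  }
  # the exact test is conservative: removal fraction <= alpha (+3 MC SE)
  expect_lte(removed / total, 0.001 + 3 * sqrt(0.001 * 0.999 / total))
})

test_that("LD pruning drops the later of correlated marker pairs", {
  sim <- simulate_cohort(sim_config(n_per_group = c(70L, 70L, 60L),
                                    n_markers = 20L, missing_rate = 0,
                                    seed = 17L))
  gt <- sim$table
  # duplicate marker 3 as marker 21
  g2 <- cbind(gt$genotypes, gt$genotypes[, 3L])
  mk <- dplyr::bind_rows(gt$markers,
                         tibble::tibble(marker = "dup", chr = "1",
                                        pos = 21000L, allele_minor = "A",
                                        allele_major = "G"))
  gtd <- geno_table(g2, mk, gt$samples)
  pr <- ld_prune(gtd)
  expect_true("dup" %in% pr$report$marker)        # later copy dropped
  expect_true(gt$markers$marker[3] %in% pr$kept)  # earlier copy kept

  # threshold 1.0: only exact duplicates dropped
  pr1 <- ld_prune(gtd, r2_threshold = 1.0)
  expect_equal(pr1$report$marker, "dup")

  # constant marker: kept, and its presence does not change the result
  gc <- cbind(gtd$genotypes, 0L)
  mkc <- dplyr::bind_rows(mk, tibble::tibble(marker = "const", chr = "1",
                                             pos = 22000L,
                                             allele_minor = "A",
                                             allele_major = "G"))
  prc <- ld_prune(geno_table(gc, mkc, gt$samples))
  expect_true("const" %in% prc$kept)
  expect_equal(setdiff(prc$kept, "const"), pr$kept)

  # pruning is a fixed point
  pr2 <- ld_prune(pr$table)
  expect_equal(pr2$kept, pr$kept)
})

test_that("independent markers are rarely pruned at r2 0.75", {
  dropped <- 0L; total <- 0L
  for (seed in 1:5) {
    sim <- simulate_cohort(sim_config(n_per_group = c(70L, 70L, 60L),
                                      n_markers = 300L, fst = 0,
                                      frac_associated = 0, missing_rate = 0,
                                      seed = 70L + seed))
    pr <- ld_prune(sim$table)
    dropped <- dropped + nrow(pr$report)
    total <- total + 300L
  }
  expect_lt(dropped / total, 0.01)
})

test_that("Mendelian check flags impossible transmissions only", {
  g <- rbind(fa = c(0L, 1L, 0L, 2L, 1L),
             mo = c(0L, 1L, 2L, 2L, 1L),
             ch = c(1L, 0L, 1L, 1L, NA))
  # col1: parents (0,0), child 1 -> inconsistent
  # col2: parents (1,1), child 0 -> consistent
  # col3: parents (0,2), child 1 -> consistent
  # col4: parents (2,2), child 1 -> inconsistent
  # col5: missing child -> skipped
  gt <- geno_table(g,
                   markers = tibble::tibble(marker = paste0("m", 1:5),
                                            chr = "1", pos = 1:5 * 10L,
                                            allele_minor = "A",
                                            allele_major = "G"),
                   samples = tibble::tibble(sample = c("fa", "mo", "ch"),
                                            group = NA_character_))
  ped <- tibble::tibble(child = "ch", father = "fa", mother = "mo")
  out <- mendel_check(gt, ped)
  expect_equal(out$n_tested, 4L)
  expect_equal(out$n_inconsistent, 2L)
  expect_equal(out$rate, 0.5)

  expect_error(mendel_check(gt, tibble::tibble(child = "ch", father = "fa",
                                               mother = "nope")),
               "absent")
})

test_that("masking harness scores imputers against the hidden truth", {
  sim <- simulate_cohort(sim_config(n_per_group = c(30L, 30L, 30L),
                                    n_markers = 40L, missing_rate = 0,
                                    seed = 13L))
  # oracle imputer: returns the truth
  truth <- sim$table
  oracle <- function(tab) truth
  out <- mask_and_concordance(sim$table, 0.05, imputer = oracle,
                              n_reps = 5L, seed = 2L)
  expect_equal(out$mean_concordance, 1.0)
  expect_equal(out$sd_concordance, 0.0)

  # a leaky imputer violates the contract
  leaky <- function(tab) tab
  expect_error(mask_and_concordance(sim$table, 0.05, imputer = leaky,
                                    n_reps = 1L, seed = 2L),
               "contract")
})

test_that("mode-imputer concordance matches the modal genotype frequency", {
  # constant column: mode imputation is perfect
  n <- 80L
  gt_const <- geno_table(matrix(1L, n, 1),
                         markers = tibble::tibble(marker = "m", chr = "1",
                                                  pos = 1L,
                                                  allele_minor = "A",
                                                  allele_major = "G"),
                         samples = tibble::tibble(sample = paste0("s", 1:n),
                                                  group = NA_character_))
  out <- mask_and_concordance(gt_const, 0.1, n_reps = 10L, seed = 3L)
  expect_equal(out$mean_concordance, 1.0)

  # binomial(2, 0.5) genotypes: the modal genotype is the heterozygote at
  # population frequency 0.5, which bounds mode-imputation concordance
  set.seed(42)
  m <- 60L; ns <- 200L
  g <- matrix(rbinom(ns * m, 2L, 0.5), ns, m)
  gt <- geno_table(g,
                   markers = tibble::tibble(marker = sprintf("b%02d", 1:m),
                                            chr = "1", pos = 1:m * 10L,
                                            allele_minor = "A",
                                            allele_major = "G"),
                   samples = tibble::tibble(sample = sprintf("s%03d", 1:ns),
                                            group = NA_character_))
  out <- mask_and_concordance(gt, 0.05, n_reps = 30L, seed = 4L)
  n_masked <- round(0.05 * ns * m)
  se <- sqrt(0.5 * 0.5 / n_masked)
  expect_lt(abs(out$mean_concordance - 0.5), 4 * se)
})

test_that("masking replicate spread is on the reported order of magnitude", {
  sim <- simulate_cohort(sim_config(n_per_group = c(70L, 70L, 65L),
                                    n_markers = 150L, missing_rate = 0,
                                    seed = 19L))
  out <- mask_and_concordance(sim$table, 0.02, n_reps = 110L, seed = 5L)
  expect_gt(out$sd_concordance, 1e-4)
  expect_lt(out$sd_concordance, 0.05)
})
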