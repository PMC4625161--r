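# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation it checks.

# Exact HWE p-value via the Wigginton recurrence from the modal
# heterozygote count (the package uses a closed-form log-gamma sum).
oracle_hwe_p <- function(n_hom1, n_het, n_hom2) {
  N <- n_hom1 + n_het + n_hom2
  rare <- 2L * min(n_hom1, n_hom2) + n_het
  if (rare == 0L) return(1)
  common <- 2L * N - rare
  hets <- seq(rare %% 2L, rare, by = 2L)
  probs <- stats::setNames(numeric(length(hets)), hets)
  mid <- floor(rare * common / (2 * N))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  probs[as.character(mid)] <- 1
  h <- mid
  while (h >= 2L) {
    # P(h-2) / P(h) = h (h-1) / ((rare - h + 2)(common - h + 2))
    probs[as.character(h - 2L)] <- probs[as.character(h)] *
      h * (h - 1) / ((rare - h + 2) * (common - h + 2))
    h <- h - 2L
  }
  h <- mid
  while (h + 2L <= rare) {
    probs[as.character(h + 2L)] <- probs[as.character(h)] *
      (rare - h) * (common - h) / ((h + 2) * (h + 1))
    h <- h + 2L
  }
  probs <- probs / sum(probs)
  p_obs <- probs[as.character(n_het)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

# Pearson chi-square on a 2x2 allele table via base R's chisq.test.
oracle_chi2 <- function(counts) {
  m <- matrix(counts, 2, 2, byrow = TRUE)
  suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic[[1]]
}

# Fraction of uniform {0,1,2} re-randomizations detectable as Mendelian
# inconsistency, by enumeration over all parent genotype pairs at allele
# frequency p (HWE parents), marginalized over the child replacement.
oracle_trio_detectable <- function(p) {
  geno_p <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  total <- 0
  for (fa in 0:2) for (mo in 0:2) {
    minc <- (fa == 2) + (mo == 2)
    maxc <- (fa >= 1) + (mo >= 1)
    p_bad_given_replace <- mean(!(0:2 >= minc & 0:2 <= maxc))
    total <- total + geno_p[fa + 1] * geno_p[mo + 1] * p_bad_given_replace
  }
  total
}

# All-pairs brute force genic annotation (quadratic; package uses an
# interval-tree overlap join).
oracle_annotate <- function(markers, genes, flank = 10000L) {
  status <- character(nrow(markers))
  hit_genes <- character(nrow(markers))
  for (i in seq_len(nrow(markers))) {
    p0 <- markers$pos[i] - 1L
    hits <- genes$gene[genes$chr == markers$chr[i] &
                         genes$start - flank <= p0 &
                         p0 < genes$end + flank]
    status[i] <- if (length(hits)) "genic" else "non-genic"
    hit_genes[i] <- if (length(hits)) paste(hits, collapse = ",") else NA
  }
  tibble::tibble(marker = markers$marker, status = status, genes = hit_genes)
}

# small labeled cohort builder for classifier tests
toy_cohort <- function(geno_by_group, markers = NULL) {
  g <- do.call(rbind, geno_by_group)
  groups <- rep(names(geno_by_group), vapply(geno_by_group, nrow, 0L))
  m <- ncol(g)
  if (is.null(markers)) markers <- sprintf("t%02d", seq_len(m))
  geno_table(
    g,
    markers = tibble::tibble(marker = markers, chr = "1",
                             pos = as.integer(seq_len(m) * 100L),
                             allele_minor = "A", allele_major = "G"),
    samples = tibble::tibble(sample = sprintf("x%03d", seq_len(nrow(g))),
                             group = groups))
}
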