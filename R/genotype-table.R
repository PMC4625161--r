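#' Construct a genotype table
#'
#' A `geno_table` is the package's universal genotype container: a
#' samples-by-markers matrix of minor-allele dosages (0, 1, 2, `NA` for
#' missing) together with marker metadata (chromosome, 1-based position,
#' minor/major allele) and sample metadata (group label, e.g. the three
#' constitutional types `"V"`, `"P"`, `"K"`).
#'
#' Minor-allele polarity is fixed once for the whole cohort (normally at
#' load time by [read_ped_map()]), so per-subgroup allele frequencies may
#' legitimately exceed 0.5.
#'
#' @param genotypes Integer matrix, samples in rows, markers in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param markers A data frame with columns `marker`, `chr`, `pos`,
#'   `allele_minor`, `allele_major`; one row per column of `genotypes`.
#' @param samples A data frame with columns `sample` and `group`
#'   (`NA` allowed); one row per row of `genotypes`.
#' @return An object of class `geno_table`.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("m1", "m2")))
#' gt <- geno_table(g,
#'                  markers = tibble::tibble(marker = c("m1", "m2"),
#'                                           chr = "1", pos = c(100L, 200L),
#'                                           allele_minor = "A",
#'                                           allele_major = "G"),
#'                  samples = tibble::tibble(sample = c("s1", "s2"),
#'                                           group = c("V", "P")))
#' gt
#' @export
geno_table <- function(genotypes, markers, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  markers <- tibble::as_tibble(markers)
  samples <- tibble::as_tibble(samples)
  stopifnot(
    nrow(genotypes) == nrow(samples),
    ncol(genotypes) == nrow(markers),
    all(c("marker", "chr", "pos", "allele_minor", "allele_major") %in%
          names(markers)),
    all(c("sample", "group") %in% names(samples))
  )
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (anyDuplicated(markers$marker)) stop("marker ids must be unique", call. = FALSE)
  if (anyDuplicated(samples$sample)) stop("sample ids must be unique", call. = FALSE)
  if (any(markers$pos < 0, na.rm = TRUE)) stop("positions must be non-negative", call. = FALSE)
  dimnames(genotypes) <- list(samples$sample, markers$marker)
  structure(list(genotypes = genotypes, markers = markers, samples = samples),
            class = "geno_table")
}

#' @export
print.geno_table <- function(x, ...) {
  grp <- x$samples$group
  cat(sprintf("<geno_table> %d samples x %d markers\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  if (any(!is.na(grp))) {
    tab <- table(grp, useNA = "ifany")
    cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_table <- function(x) dim(x$genotypes)

n_samples <- function(x) nrow(x$genotypes)
n_markers <- function(x) ncol(x$genotypes)

#' Subset a genotype table
#'
#' @param table A [geno_table()].
#' @param samples,markers Character vectors of ids to keep (`NULL` keeps all).
#'   Order of the request is preserved.
#' @return A `geno_table` restricted to the requested samples and markers.
#' @export
subset_geno <- function(table, samples = NULL, markers = NULL) {
  stopifnot(inherits(table, "geno_table"))
  si <- if (is.null(samples)) seq_len(n_samples(table)) else {
    i <- match(samples, table$samples$sample)
    if (anyNA(i)) stop("unknown sample id(s): ",
                       paste(samples[is.na(i)], collapse = ", "), call. = FALSE)
    i
  }
  mi <- if (is.null(markers)) seq_len(n_markers(table)) else {
    i <- match(markers, table$markers$marker)
    if (anyNA(i)) stop("unknown marker id(s): ",
                       paste(markers[is.na(i)], collapse = ", "), call. = FALSE)
    i
  }
  geno_table(table$genotypes[si, mi, drop = FALSE],
             table$markers[mi, ], table$samples[si, ])
}

#' Tidy a genotype table into long form
#'
#' @param x A [geno_table()].
#' @param ... Unused.
#' @return A tibble with one row per (sample, marker) cell: `sample`,
#'   `group`, `marker`, `genotype`.
#' @method tidy geno_table
#' @export
tidy.geno_table <- function(x, ...) {
  tibble::tibble(
    sample = rep(x$samples$sample, times = n_markers(x)),
    group = rep(x$samples$group, times = n_markers(x)),
    marker = rep(x$markers$marker, each = n_samples(x)),
    genotype = as.integer(x$genotypes)
  )
}

#' Minor allele frequency of markers in a sample subset
#'
#' Computes (count of minor alleles) / (2 x non-missing samples) per marker.
#' Polarity is whatever the table carries (fixed cohort-wide at load), so a
#' subgroup frequency may exceed 0.5.
#'
#' @param table A [geno_table()].
#' @param markers Marker ids (default: all).
#' @param samples Sample ids defining the subset (default: all).
#' @return A tibble with columns `marker`, `n_called` (non-missing samples),
#'   `maf` (`NA` if the marker is missing in every subset sample).
#' @examples
#' sim <- simulate_cohort(sim_config(n_markers = 5, seed = 1))
#' minor_allele_freq(sim$table)
#' @export
minor_allele_freq <- function(table, markers = NULL, samples = NULL) {
  gt <- subset_geno(table, samples = samples, markers = markers)
  g <- gt$genotypes
  n_called <- colSums(!is.na(g))
  if (nrow(g) == 0L) stop("sample subset is empty", call. = FALSE)
  maf <- colSums(g, na.rm = TRUE) / (2 * n_called)
  maf[n_called == 0L] <- NA_real_
  tibble::tibble(marker = gt$markers$marker,
                 n_called = as.integer(n_called), maf = unname(maf))
}

#' Per-sample genotype call rate
#'
#' @param table A [geno_table()].
#' @return A tibble with columns `sample` and `call_rate` (fraction of
#'   non-missing genotypes).
#' @export
sample_call_rate <- function(table) {
  stopifnot(inherits(table, "geno_table"))
  tibble::tibble(sample = table$samples$sample,
                 call_rate = unname(rowMeans(!is.na(table$genotypes))))
}

# sample ids belonging to a set of group labels
group_samples <- function(table, groups) {
  table$samples$sample[!is.na(table$samples$group) &
                         table$samples$group %in% groups]
}

# the three one-vs-rest comparisons; case group first
comparison_groups <- function() {
  list(V_vs_PK = list(case = "V", control = c("P", "K")),
       P_vs_VK = list(case = "P", control = c("V", "K")),
       K_vs_VP = list(case = "K", control = c("V", "P")))
}
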