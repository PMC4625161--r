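#' Read PLINK text PED/MAP files into a genotype table
#'
#' Parses the whitespace-delimited PLINK text format: the MAP file gives one
#' marker per line (`chr id cM pos`), the PED file one sample per line with
#' six leading columns (`FID IID PAT MAT SEX PHENO`) followed by two allele
#' columns per marker. The allele code `"0"` means missing.
#'
#' The minor allele of each marker is determined once from allele counts
#' over the whole file (ties at frequency 0.5 are broken to the
#' alphabetically later allele), and genotypes are coded as the minor-allele
#' dosage. Per-subgroup frequencies computed later inherit this polarity.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @param group_map Named character vector mapping PED phenotype strings to
#'   group labels, e.g. `c("1" = "V", "2" = "P", "3" = "K")`. By default the
#'   phenotype string itself is used, with `"0"`, `"-9"` and `"NA"` read as
#'   no label.
#' @return A [geno_table()].
#' @seealso [write_ped_map()]
#' @export
read_ped_map <- function(ped_path, map_path, group_map = NULL) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- if (any(nzchar(trimws(readLines(map_path))))) {
    utils::read.table(map_path, colClasses = "character")
  } else {
    data.frame(V1 = character(), V2 = character(), V3 = character(),
               V4 = character())
  }
  if (ncol(map) < 4L) stop("MAP file must have 4 columns", call. = FALSE)
  m <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  nf <- lengths(fields)
  if (length(nf) && any(nf != 6L + 2L * m)) {
    stop(sprintf("PED line has %d fields; expected %d for %d markers",
                 nf[which(nf != 6L + 2L * m)[1]], 6L + 2L * m, m),
         call. = FALSE)
  }
  n <- length(fields)
  ped <- matrix(unlist(fields), nrow = max(n, 0L), byrow = TRUE)

  sample_id <- if (n) ped[, 2L] else character()
  pheno <- if (n) ped[, 6L] else character()
  group <- if (is.null(group_map)) {
    ifelse(pheno %in% c("0", "-9", "NA"), NA_character_, pheno)
  } else {
    unname(group_map[pheno])
  }

  a1 <- if (n) ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE] else
    matrix(character(), 0L, m)
  a2 <- if (n) ped[, 6L + 2L * seq_len(m), drop = FALSE] else
    matrix(character(), 0L, m)

  geno <- matrix(NA_integer_, n, m)
  allele_minor <- allele_major <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- c(x1[x1 != "0"], x2[x2 != "0"])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L) {
      stop(sprintf("marker %s has >2 alleles: %s", map[j, 2L],
                   paste(alleles, collapse = ",")), call. = FALSE)
    }
    if (length(alleles) == 0L) alleles <- c("N", "N")
    if (length(alleles) == 1L) alleles <- c(alleles, alleles)
    cnt <- c(sum(obs == alleles[1L]), sum(obs == alleles[2L]))
    # minor = rarer allele; tie broken to the alphabetically later allele
    minor <- if (cnt[1L] < cnt[2L]) alleles[1L] else alleles[2L]
    major <- setdiff(alleles, minor)
    if (length(major) == 0L) major <- minor
    allele_minor[j] <- minor
    allele_major[j] <- major[1L]
    d <- (x1 == minor) + (x2 == minor)
    d[x1 == "0" | x2 == "0"] <- NA_integer_
    geno[, j] <- as.integer(d)
  }

  geno_table(
    geno,
    markers = tibble::tibble(marker = map[, 2L], chr = map[, 1L],
                             pos = as.integer(map[, 4L]),
                             allele_minor = allele_minor,
                             allele_major = allele_major),
    samples = tibble::tibble(sample = sample_id, group = group)
  )
}

#' Write a genotype table to PLINK text PED/MAP files
#'
#' Round-trip property: `read_ped_map()` of the written files recovers the
#' genotype matrix exactly (up to allele-label polarity at markers where the
#' written alleles are equally frequent).
#'
#' @param table A [geno_table()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(table, ped_path, map_path) {
  stopifnot(inherits(table, "geno_table"))
  mk <- table$markers
  utils::write.table(
    data.frame(mk$chr, mk$marker, rep(0, nrow(mk)), mk$pos),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  g <- table$genotypes
  n <- nrow(g); m <- ncol(g)
  lines <- character(n)
  minor <- mk$allele_minor; major <- mk$allele_major
  for (i in seq_len(n)) {
    gi <- g[i, ]
    x1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1L, minor, major))
    x2 <- ifelse(is.na(gi), "0", ifelse(gi == 2L, minor, major))
    ph <- table$samples$group[i]
    if (is.na(ph)) ph <- "-9"
    lines[i] <- paste(c(paste0("F", i), table$samples$sample[i], "0", "0",
                        "1", ph, as.vector(rbind(x1, x2))), collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read gene intervals from a BED file
#'
#' BED coordinates are half-open and 0-based; they are stored exactly as
#' read. A fourth column, when present, supplies the gene name; otherwise
#' names `region_1, region_2, ...` are generated.
#'
#' @param path Path to a BED3+ text file.
#' @return A tibble with columns `chr`, `start`, `end`, `gene`, in file
#'   order.
#' @export
read_bed_intervals <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble::tibble(chr = character(), start = integer(),
                          end = integer(), gene = character()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(fields) < 3L)) stop("BED lines need >= 3 columns", call. = FALSE)
  chr <- vapply(fields, `[`, "", 1L)
  start <- as.integer(vapply(fields, `[`, "", 2L))
  end <- as.integer(vapply(fields, `[`, "", 3L))
  gene <- vapply(seq_along(fields), function(i) {
    if (lengths(fields)[i] >= 4L) fields[[i]][4L] else paste0("region_", i)
  }, "")
  if (any(start >= end)) {
    stop("BED interval with start >= end at line ",
         which(start >= end)[1L], call. = FALSE)
  }
  tibble::tibble(chr = chr, start = start, end = end, gene = gene)
}

#' Export a genotype table as TSV
#'
#' Writes a wide table (one row per sample: `sample`, `group`, then one
#' column per marker) that [read_geno_tsv()] reads back. Missing genotypes
#' are written as `NA`. Marker metadata travels in a sidecar written next to
#' the genotype file with suffix `.markers.tsv`.
#'
#' @param table A [geno_table()].
#' @param path Output path for the genotype TSV.
#' @return Invisibly, `path`.
#' @export
write_geno_tsv <- function(table, path) {
  stopifnot(inherits(table, "geno_table"))
  wide <- dplyr::bind_cols(table$samples,
                           tibble::as_tibble(table$genotypes))
  readr::write_tsv(wide, path, na = "NA")
  readr::write_tsv(table$markers, paste0(path, ".markers.tsv"))
  invisible(path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(sample = "c", group = "c",
                                                  .default = "i"))
  markers <- readr::read_tsv(paste0(path, ".markers.tsv"),
                             show_col_types = FALSE,
                             col_types = readr::cols(marker = "c", chr = "c",
                                                     pos = "i",
                                                     .default = "c"))
  geno_table(as.matrix(wide[, markers$marker, drop = FALSE]),
             markers, wide[, c("sample", "group")])
}
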