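#' Annotate markers as genic or non-genic by flanking-window overlap
#'
#' A marker at 1-based position p is genic for a gene interval
#' `[start, end)` (BED half-open, 0-based) when
#' `start - flank <= p - 1 < end + flank`; the boundary at exactly `flank`
#' is inclusive, matching `bedtools window`. All overlapping genes are
#' listed comma-joined in input order.
#'
#' @param markers Tibble with columns `marker`, `chr`, `pos` (1-based), as
#'   in a [geno_table()]'s `$markers`.
#' @param genes Gene intervals from [read_bed_intervals()].
#' @param flank Flanking window in bases (default 10000).
#' @return A tibble `marker`, `status` (`"genic"`/`"non-genic"`), `genes`
#'   (comma-joined names, `NA` for non-genic).
#' @export
annotate_markers <- function(markers, genes, flank = 10000L) {
  stopifnot(all(c("marker", "chr", "pos") %in% names(markers)),
            all(c("chr", "start", "end", "gene") %in% names(genes)),
            flank >= 0L)
  unknown <- setdiff(unique(markers$chr), unique(genes$chr))
  if (length(unknown) && nrow(genes)) {
    warning("marker chromosome(s) absent from gene set: ",
            paste(unknown, collapse = ", "), " (treated as non-genic)")
  }
  genes_hit <- rep(NA_character_, nrow(markers))
  if (nrow(genes) && nrow(markers)) {
    q <- GenomicRanges::GRanges(markers$chr,
                                IRanges::IRanges(markers$pos, markers$pos))
    s <- GenomicRanges::GRanges(genes$chr,
                                IRanges::IRanges(genes$start + 1L, genes$end))
    # maxgap counts bases strictly between the ranges, so the inclusive
    # "within flank" rule needs flank - 1 (and -1 means plain overlap)
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(q, s, maxgap = flank - 1L))
    hits <- tibble::tibble(mi = S4Vectors::queryHits(ov),
                           gi = S4Vectors::subjectHits(ov))
    hits <- dplyr::arrange(hits, .data$mi, .data$gi)   # input order
    if (nrow(hits)) {
      joined <- dplyr::summarise(
        dplyr::group_by(hits, .data$mi),
        genes = paste(genes$gene[.data$gi], collapse = ","))
      genes_hit[joined$mi] <- joined$genes
    }
  }
  tibble::tibble(marker = markers$marker,
                 status = ifelse(is.na(genes_hit), "non-genic", "genic"),
                 genes = genes_hit)
}

#' Per-group genic/non-genic panel summary
#'
#' @param records Annotation records from [annotate_markers()] covering all
#'   panel markers.
#' @param panels Named list of marker-id panels (as given to
#'   [fit_weight_model()]).
#' @return A tibble per group: `group`, `n_markers`, `n_genic`,
#'   `n_nongenic`, `n_genes` (distinct genes), `genes` (comma-joined).
#' @export
summarize_panel <- function(records, panels) {
  purrr::imap_dfr(panels, function(mk, grp) {
    sub <- records[match(mk, records$marker), , drop = FALSE]
    if (anyNA(sub$marker)) {
      stop("annotation records do not cover panel ", grp, call. = FALSE)
    }
    gene_list <- unique(unlist(strsplit(sub$genes[!is.na(sub$genes)], ",")))
    tibble::tibble(group = grp, n_markers = nrow(sub),
                   n_genic = sum(sub$status == "genic"),
                   n_nongenic = sum(sub$status == "non-genic"),
                   n_genes = length(gene_list),
                   genes = paste(gene_list, collapse = ","))
  })
}
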