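#' Find candidate cis-target genes near intergenic lncRNAs
#'
#' For each intergenic lncRNA (lincRNA), reports every protein-coding gene
#' whose locus intersects the window extending `window` bp up- and
#' downstream of the lincRNA locus, i.e. `[start - window, end + window)`
#' on the same chromosome. A gene whose nearest edge is exactly `window`
#' bp away is excluded; `window - 1` bp is included. Distances are
#' edge-to-edge and signed relative to the lincRNA's strand: negative when
#' the gene lies upstream of the lincRNA 5' end, positive downstream.
#'
#' @param lincs Annotation tibble of lncRNAs expected to be intergenic.
#' @param genes Annotation tibble of protein-coding genes.
#' @param window Window size in bp on each side (default 10000).
#' @param labels Optional output of [classify_lncrnas()] used to verify the
#'   intergenic precondition; computed internally from `genes` when absent.
#' @param lenient When `TRUE`, non-intergenic input lncRNAs are dropped
#'   with a warning instead of raising an error.
#' @return A tibble with columns `lincRNA_id`, `gene_id`,
#'   `signed_distance`, `orientation` (`same_strand`/`opposite_strand`).
#' @export
find_nearby_genes <- function(lincs, genes, window = 10000, labels = NULL,
                              lenient = FALSE) {
  if (!is.numeric(window) || window <= 0) stop("window must be > 0", call. = FALSE)
  empty <- tibble::tibble(lincRNA_id = character(0), gene_id = character(0),
                          signed_distance = integer(0), orientation = character(0))
  if (nrow(lincs) == 0) return(empty)
  if (is.null(labels)) labels <- classify_lncrnas(lincs, genes)
  lab <- labels$subtype[match(lincs$transcript_id, labels$transcript_id)]
  if (anyNA(lab)) {
    stop("no classification label for: ",
         paste(lincs$transcript_id[is.na(lab)], collapse = ", "), call. = FALSE)
  }
  bad <- lab != "intergenic"
  if (any(bad)) {
    if (lenient) {
      warning("dropping non-intergenic lncRNAs: ",
              paste(lincs$transcript_id[bad], collapse = ", "), call. = FALSE)
      lincs <- lincs[!bad, , drop = FALSE]
      if (nrow(lincs) == 0) return(empty)
    } else {
      stop("non-intergenic lncRNAs in input: ",
           paste(lincs$transcript_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(genes) == 0) return(empty)
  g_by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  rows <- list()
  for (i in seq_len(nrow(lincs))) {
    gi <- g_by_chrom[[lincs$chrom[i]]]
    if (is.null(gi)) next
    span <- c(lincs$start[i], lincs$end[i])
    gspan <- cbind(genes$start[gi], genes$end[gi])
    gaps <- gap_bp(matrix(span, ncol = 2), gspan)
    ovs <- overlap_bp(matrix(span, ncol = 2), gspan)
    hit <- which(gaps < window)
    if (length(hit) == 0) next
    # intergenic lincRNAs never overlap a gene, so distance is the gap,
    # signed by which flank of the lincRNA the gene sits on
    upstream <- if (lincs$strand[i] == "+") {
      gspan[hit, 2] <= span[1]
    } else {
      gspan[hit, 1] >= span[2]
    }
    stopifnot(all(ovs[hit] == 0))
    rows[[length(rows) + 1]] <- tibble::tibble(
      lincRNA_id = lincs$transcript_id[i],
      gene_id = genes$transcript_id[gi[hit]],
      signed_distance = as.integer(ifelse(upstream, -gaps[hit], gaps[hit])),
      orientation = ifelse(genes$strand[gi[hit]] == lincs$strand[i],
                           "same_strand", "opposite_strand")
    )
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Summarize a cis-pair table
#'
#' @param pairs Output of [find_nearby_genes()].
#' @param n_lincs Optional total number of intergenic lncRNAs searched,
#'   enabling the co-localization percentage.
#' @param decimals Decimal places for the percentage (default 1).
#' @return A list with `n_pairs`, `n_lincs_with_partner`,
#'   `n_partner_genes` and, when `n_lincs` is given, `pct_colocalized`.
#' @export
cis_summary <- function(pairs, n_lincs = NULL, decimals = 1) {
  out <- list(
    n_pairs = nrow(pairs),
    n_lincs_with_partner = length(unique(pairs$lincRNA_id)),
    n_partner_genes = length(unique(pairs$gene_id))
  )
  if (!is.null(n_lincs)) {
    out$pct_colocalized <- proportion(out$n_lincs_with_partner, n_lincs, decimals)
  }
  out
}
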