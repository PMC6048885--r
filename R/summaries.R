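.round_half_up <- function(x, decimals = 0) {
  f <- 10^decimals
  floor(x * f + 0.5) / f
}

#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` places,
#' matching the convention of printed report tables (e.g. 1607 of 14,256
#' at 0 decimals is 11; 194 of 829 at 1 decimal is 23.4).
#'
#' @param numerator,denominator Non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`; vectorized.
#' @param decimals Decimal places (default 1).
#' @return Numeric percentage(s).
#' @export
proportion <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) stop("denominator must be > 0", call. = FALSE)
  if (any(numerator < 0)) stop("numerator must be >= 0", call. = FALSE)
  if (any(numerator > denominator)) {
    stop("numerator must not exceed denominator", call. = FALSE)
  }
  .round_half_up(100 * numerator / denominator, decimals)
}

#' Per-chromosome specific-to-expressed ratios
#'
#' For each chromosome, counts the transcripts expressed in the focal
#' tissue and those called specific to it, split by biotype, and reports
#' the enrichment ratio specific/total per biotype. Chromosomes with no
#' expressed transcripts of a biotype get ratio 0 and a degenerate flag.
#'
#' @param calls Output of [call_specific()].
#' @param annotations Annotation tibble covering at least every transcript
#'   called specific (missing annotations are an error).
#' @param tissue Focal tissue (default `"testis"`).
#' @param expressed_ids Optional character vector restricting the totals to
#'   transcripts expressed in the focal tissue (e.g. from
#'   [expressed_in()]); default: all annotated transcripts.
#' @return A tibble with one row per chromosome: totals, specific counts
#'   and ratios per biotype, plus `degenerate_lnc`/`degenerate_mrna` flags
#'   for zero denominators.
#' @export
chrom_distribution <- function(calls, annotations, tissue = "testis",
                               expressed_ids = NULL) {
  spec_ids <- calls$transcript_id[calls$is_specific &
                                    calls$target_tissue == tissue]
  missing_ann <- setdiff(spec_ids, annotations$transcript_id)
  if (length(missing_ann) > 0) {
    stop("specific transcripts without annotation: ",
         paste(missing_ann, collapse = ", "), call. = FALSE)
  }
  ann <- annotations
  if (!is.null(expressed_ids)) {
    ann <- ann[ann$transcript_id %in% expressed_ids, , drop = FALSE]
  }
  chroms <- unique(ann$chrom)
  one <- function(ch) {
    sub <- ann[ann$chrom == ch, , drop = FALSE]
    is_lnc <- sub$biotype == "lncRNA"
    n_tot_l <- sum(is_lnc)
    n_tot_m <- sum(!is_lnc)
    n_sp_l <- sum(is_lnc & sub$transcript_id %in% spec_ids)
    n_sp_m <- sum(!is_lnc & sub$transcript_id %in% spec_ids)
    tibble::tibble(
      chrom = ch,
      n_total_lnc = n_tot_l, n_specific_lnc = n_sp_l,
      n_total_mrna = n_tot_m, n_specific_mrna = n_sp_m,
      ratio_lnc = if (n_tot_l > 0) n_sp_l / n_tot_l else 0,
      ratio_mrna = if (n_tot_m > 0) n_sp_m / n_tot_m else 0,
      degenerate_lnc = n_tot_l == 0,
      degenerate_mrna = n_tot_m == 0
    )
  }
  do.call(rbind, lapply(chroms, one))
}

#' Venn-style overlap of named transcript sets
#'
#' Partitions the union of two or more named id sets into exclusive Venn
#' regions and counts each region, the union and the full intersection.
#' Duplicate ids within a set are collapsed with a warning.
#'
#' @param sets Named list (>= 2 elements) of character vectors.
#' @return A list with `regions` (tibble of `region`, `degree`, `n`, one
#'   row per non-empty combination of set names, zero counts included),
#'   `union_size` and `intersection_size`. Region counts always sum to the
#'   union size.
#' @export
set_overlap <- function(sets) {
  if (length(sets) < 2) stop("need >= 2 sets", call. = FALSE)
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm) > 0) {
    stop("sets must have unique non-empty names", call. = FALSE)
  }
  sets <- lapply(nm, function(s) {
    v <- sets[[s]]
    if (anyDuplicated(v) > 0) {
      warning("duplicate ids in set '", s, "' collapsed", call. = FALSE)
      v <- unique(v)
    }
    v
  })
  names(sets) <- nm
  ids <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  memb <- matrix(memb, nrow = length(ids), dimnames = list(NULL, nm))
  key <- apply(memb, 1, function(r) paste(nm[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(nm), function(d) {
    utils::combn(nm, d, paste, collapse = "&")
  }))
  degree <- unlist(lapply(seq_along(nm), function(d) {
    rep(d, choose(length(nm), d))
  }))
  n <- vapply(combos, function(k) sum(key == k), integer(1))
  list(
    regions = tibble::tibble(region = combos, degree = degree,
                             n = unname(n)),
    union_size = length(ids),
    intersection_size = sum(rowSums(memb) == ncol(memb))
  )
}

.STAGES <- c("mitotic_or_earlier", "early_spermatocyte",
             "pachytene_spermatocyte", "round_spermatid", "undetected")

#' Default postnatal sampling days for the first spermatogenic wave
#' @return Integer vector of postnatal days.
#' @export
default_stage_days <- function() c(7L, 8L, 14L, 16L, 21L, 24L, 28L, 35L, 42L, 49L, 56L)

#' Infer the spermatogenic stage from first detection day
#'
#' During the synchronized first round of spermatogenesis, successive
#' postnatal days correspond to successive germ-cell stages: meiosis begins
#' around day 10, pachytene spermatocytes are enriched by day 14, and round
#' spermatids appear at day 18. A transcript's first detection day
#' therefore dates the earliest stage expressing it. The default cutoffs
#' map day <= 10 to `mitotic_or_earlier`, days 11-14 to
#' `early_spermatocyte`, days 15-16 to `pachytene_spermatocyte`, and any
#' later day to `round_spermatid`; no detection on any sampled day yields
#' `undetected`.
#'
#' @param detected Logical vector of detection by day, optionally named by
#'   postnatal day (names override `days`).
#' @param days Postnatal days sampled, ascending; default
#'   [default_stage_days()].
#' @param boundaries Upper day bounds (inclusive) of the first three
#'   stages, ascending.
#' @return A list with `first_detection_day` (`NA` when undetected) and
#'   `inferred_stage`.
#' @export
stage_assignment <- function(detected, days = default_stage_days(),
                             boundaries = c(mitotic_or_earlier = 10,
                                            early_spermatocyte = 14,
                                            pachytene_spermatocyte = 16)) {
  if (!is.null(names(detected))) days <- as.numeric(names(detected))
  if (length(days) == 0) stop("empty day set", call. = FALSE)
  if (length(days) != length(detected)) {
    stop("days and detected must have equal length", call. = FALSE)
  }
  if (length(boundaries) != 3 || is.unsorted(boundaries, strictly = TRUE)) {
    stop("boundaries must be three ascending day cutoffs", call. = FALSE)
  }
  o <- order(days)
  days <- days[o]
  detected <- as.logical(detected)[o]
  if (!any(detected)) {
    return(list(first_detection_day = NA_integer_, inferred_stage = "undetected"))
  }
  first <- days[which(detected)[1]]
  stage <- if (first <= boundaries[1]) {
    "mitotic_or_earlier"
  } else if (first <= boundaries[2]) {
    "early_spermatocyte"
  } else if (first <= boundaries[3]) {
    "pachytene_spermatocyte"
  } else {
    "round_spermatid"
  }
  list(first_detection_day = as.integer(first), inferred_stage = stage)
}

#' Germ-cell specificity from wild-type versus germ-cell-deficient testis
#'
#' A transcript present in wild-type testis but absent from the
#' germ-cell-lacking testis of W/Wv (c-kit) mutant mice is inferred to be
#' germ-cell specific; a transcript still present in the mutant may also be
#' expressed in testicular somatic cells.
#'
#' @param present_wildtype,present_mutant Logical vectors (recycled).
#' @param transcript_id Optional ids for the output.
#' @return A tibble with columns `transcript_id` (if given),
#'   `present_wildtype`, `present_mutant`, `germ_cell_specific`.
#' @export
germ_cell_call <- function(present_wildtype, present_mutant,
                           transcript_id = NULL) {
  n <- max(length(present_wildtype), length(present_mutant))
  pw <- rep_len(as.logical(present_wildtype), n)
  pm <- rep_len(as.logical(present_mutant), n)
  if (anyNA(pw) || anyNA(pm)) stop("presence calls must be TRUE/FALSE", call. = FALSE)
  out <- tibble::tibble(present_wildtype = pw, present_mutant = pm,
                        germ_cell_specific = pw & !pm)
  if (!is.null(transcript_id)) {
    out <- tibble::tibble(transcript_id = rep_len(transcript_id, n), out)
  }
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Relative quantification of qPCR data: the target gene's Ct is
#' normalized to a reference gene within each sample, the calibrator
#' sample's normalized value is subtracted, and the result is expressed as
#' a linear fold-change `2^-ddCt`.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene
#'   in the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Ct of target and
#'   reference gene in the calibrator sample.
#' @return Linear relative expression (1 when sample equals calibrator);
#'   vectorized.
#' @examples
#' ddct_quantify(20, 18, 25, 18)  # 32
#' @export
ddct_quantify <- function(ct_target_sample, ct_ref_sample,
                          ct_target_calibrator, ct_ref_calibrator) {
  cts <- cbind(ct_target_sample, ct_ref_sample,
               ct_target_calibrator, ct_ref_calibrator)
  if (anyNA(cts) || any(!is.finite(cts))) {
    stop("all Ct values must be finite", call. = FALSE)
  }
  ddct <- (cts[, 1] - cts[, 2]) - (cts[, 3] - cts[, 4])
  unname(2^(-ddct))
}
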