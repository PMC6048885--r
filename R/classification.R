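.SUBTYPES <- c("exonic_sense", "exonic_antisense", "intronic_sense",
               "intronic_antisense", "bidirectional", "intergenic")

# total bp of intersection between two sets of sorted non-overlapping intervals
.iset_overlap <- function(A, B) {
  if (nrow(A) == 0 || nrow(B) == 0) return(0L)
  total <- 0L
  for (r in seq_len(nrow(A))) {
    total <- total +
      sum(pmax(0, pmin(A[r, 2], B[, 2]) - pmax(A[r, 1], B[, 1])))
  }
  as.integer(total)
}

#' Classify lncRNAs into six positional subtypes
#'
#' Assigns each lncRNA exactly one label relative to a set of
#' protein-coding genes, by precedence:
#'
#' 1. *exonic* (sense/antisense): the lncRNA locus overlaps >= 1 bp of an
#'    exon of a gene on the same chromosome;
#' 2. *intronic* (sense/antisense): it overlaps >= 1 bp of an intron but no
#'    exon;
#' 3. *bidirectional*: no overlap, but the nearest gene locus is less than
#'    `bidirectional_gap` bp away (default 1 kb), regardless of strand;
#' 4. *intergenic* (lincRNA): at least `bidirectional_gap` bp from every
#'    gene.
#'
#' Sense versus antisense compares the lncRNA strand with the partner
#' gene's. The partner is the gene with the largest overlap, then the
#' smallest gap, then the lexicographically smallest id. By default the
#' lncRNA is represented by its full transcript span; `region =
#' "exon_union"` restricts it to its exons instead.
#'
#' @param lncs Annotation tibble of lncRNAs (biotype `"lncRNA"`).
#' @param genes Annotation tibble of protein-coding genes (biotype
#'   `"mRNA"`); may have zero rows, making every lncRNA intergenic.
#' @param region `"span"` (default) or `"exon_union"`.
#' @param bidirectional_gap Distance bound in bp for the bidirectional
#'   class, exclusive (default 1000: a gap of exactly 1 kb is intergenic).
#' @return A tibble with one row per lncRNA: `transcript_id`, `subtype`,
#'   `partner_gene_id`, `evidence` (`exon_overlap`, `intron_overlap`,
#'   `proximity` or `none`), `overlap_bp`, `gap_bp`.
#' @export
classify_lncrnas <- function(lncs, genes, region = c("span", "exon_union"),
                             bidirectional_gap = 1000) {
  region <- match.arg(region)
  if (nrow(lncs) == 0) {
    return(tibble::tibble(transcript_id = character(0), subtype = character(0),
                          partner_gene_id = character(0), evidence = character(0),
                          overlap_bp = integer(0), gap_bp = integer(0)))
  }
  if (anyDuplicated(lncs$transcript_id) > 0) {
    stop("duplicate lncRNA transcript ids", call. = FALSE)
  }
  if (!all(lncs$biotype == "lncRNA")) {
    stop("lncs must all have biotype 'lncRNA'", call. = FALSE)
  }
  if (nrow(genes) > 0 && !all(genes$biotype == "mRNA")) {
    stop("genes must all have biotype 'mRNA'", call. = FALSE)
  }
  g_by_chrom <- if (nrow(genes) > 0) {
    split(seq_len(nrow(genes)), genes$chrom)
  } else {
    list()
  }
  g_introns <- lapply(genes$exons, introns_of)

  out <- vector("list", nrow(lncs))
  for (i in seq_len(nrow(lncs))) {
    gi <- g_by_chrom[[lncs$chrom[i]]]
    span <- c(lncs$start[i], lncs$end[i])
    if (is.null(gi)) {
      out[[i]] <- list(subtype = "intergenic", partner = NA_character_,
                       evidence = "none", ov = 0L, gap = NA_integer_)
      next
    }
    liv <- if (region == "span") matrix(span, ncol = 2) else lncs$exons[[i]]
    exov <- integer(length(gi))
    inov <- integer(length(gi))
    gaps <- integer(length(gi))
    for (j in seq_along(gi)) {
      g <- gi[j]
      exov[j] <- .iset_overlap(liv, genes$exons[[g]])
      inov[j] <- .iset_overlap(liv, g_introns[[g]])
      gaps[j] <- gap_bp(span, c(genes$start[g], genes$end[g]))
    }
    gid <- genes$transcript_id[gi]
    sense <- function(j) {
      if (lncs$strand[i] == genes$strand[gi[j]]) "sense" else "antisense"
    }
    if (any(exov > 0)) {
      cand <- which(exov > 0)
      j <- cand[order(-exov[cand], gaps[cand], gid[cand])][1]
      out[[i]] <- list(subtype = paste0("exonic_", sense(j)), partner = gid[j],
                       evidence = "exon_overlap", ov = exov[j], gap = gaps[j])
    } else if (any(inov > 0)) {
      cand <- which(inov > 0)
      j <- cand[order(-inov[cand], gaps[cand], gid[cand])][1]
      out[[i]] <- list(subtype = paste0("intronic_", sense(j)), partner = gid[j],
                       evidence = "intron_overlap", ov = inov[j], gap = gaps[j])
    } else {
      j <- order(gaps, gid)[1]
      if (gaps[j] < bidirectional_gap) {
        out[[i]] <- list(subtype = "bidirectional", partner = gid[j],
                         evidence = "proximity", ov = 0L, gap = gaps[j])
      } else {
        out[[i]] <- list(subtype = "intergenic", partner = gid[j],
                         evidence = "none", ov = 0L, gap = gaps[j])
      }
    }
  }
  tibble::tibble(
    transcript_id = lncs$transcript_id,
    subtype = vapply(out, `[[`, character(1), "subtype"),
    partner_gene_id = vapply(out, `[[`, character(1), "partner"),
    evidence = vapply(out, `[[`, character(1), "evidence"),
    overlap_bp = vapply(out, `[[`, integer(1), "ov"),
    gap_bp = vapply(out, `[[`, integer(1), "gap")
  )
}

#' Subtype counts and percentages
#'
#' Counts per positional subtype with half-up-rounded percentages. The six
#' labels partition the input, so the unrounded percentages sum to 100.
#'
#' @param labels Output of [classify_lncrnas()] (or any tibble with a
#'   `subtype` column), possibly subset to a transcript set of interest.
#' @param decimals Decimal places for percentages (default 1).
#' @return A tibble with columns `subtype`, `n`, `pct`; zero rows for an
#'   empty input.
#' @export
subtype_proportions <- function(labels, decimals = 1) {
  if (nrow(labels) == 0) {
    return(tibble::tibble(subtype = character(0), n = integer(0),
                          pct = numeric(0)))
  }
  n <- table(factor(labels$subtype, levels = .SUBTYPES))
  tibble::tibble(
    subtype = .SUBTYPES,
    n = as.integer(n),
    pct = proportion(as.integer(n), nrow(labels), decimals)
  )
}
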