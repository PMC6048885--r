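#' Interval overlap in base pairs
#'
#' Number of bases shared by two genomic intervals in the package-wide
#' 0-based half-open convention. Intervals on different chromosomes never
#' share bases; callers are expected to compare intervals within one
#' chromosome (or treat cross-chromosome overlap as 0).
#'
#' @param a,b Intervals as numeric vectors `c(start, end)` or two-column
#'   matrices (one interval per row; the shorter argument is recycled).
#' @return Integer vector of overlapping base counts (>= 0).
#' @examples
#' overlap_bp(c(0, 10), c(5, 20))   # 5
#' overlap_bp(c(0, 10), c(10, 20))  # 0, half-open adjacency
#' @export
overlap_bp <- function(a, b) {
  a <- .as_interval_matrix(a)
  b <- .as_interval_matrix(b)
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  as.integer(pmax(0, pmin(a[ai, 2], b[bi, 2]) - pmax(a[ai, 1], b[bi, 1])))
}

#' Gap between two intervals in base pairs
#'
#' Bases strictly between two intervals on the same chromosome: 0 when they
#' overlap or abut. Under this convention "less than 1 kb apart" means
#' `gap_bp(a, b) < 1000`.
#'
#' @inheritParams overlap_bp
#' @return Integer vector of gap sizes (>= 0).
#' @examples
#' gap_bp(c(0, 10), c(1010, 1020))  # 1000
#' gap_bp(c(0, 10), c(10, 20))      # 0, abutting
#' @export
gap_bp <- function(a, b) {
  a <- .as_interval_matrix(a)
  b <- .as_interval_matrix(b)
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  as.integer(pmax(0, pmax(a[ai, 1], b[bi, 1]) - pmin(a[ai, 2], b[bi, 2])))
}

.as_interval_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 2)
    return(x)
  }
  if (length(x) != 2) stop("an interval is c(start, end)", call. = FALSE)
  matrix(as.numeric(x), ncol = 2)
}

#' Introns of an exon set
#'
#' Gaps between consecutive exons, as a two-column matrix of 0-based
#' half-open intervals. Single-exon transcripts have no introns.
#'
#' @param exons Two-column matrix of sorted, non-overlapping exon intervals.
#' @return Two-column matrix with zero or more intron rows.
#' @export
introns_of <- function(exons) {
  exons <- .as_interval_matrix(exons)
  if (nrow(exons) < 2) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = exons[-nrow(exons), 2], end = exons[-1, 1])
}

.BIOTYPES <- c("lncRNA", "mRNA")

default_biotype_map <- function() {
  c(lncRNA = "lncRNA", lincRNA = "lncRNA", antisense = "lncRNA",
    antisense_RNA = "lncRNA", processed_transcript = "lncRNA",
    protein_coding = "mRNA", mRNA = "mRNA")
}

#' Validate a transcript annotation table
#'
#' Checks the structural invariants of the internal annotation
#' representation: 0-based half-open coordinates with `start < end`, strands
#' in `{+, -}`, exons sorted, non-overlapping and contained in the
#' transcript span, unique transcript ids, and the minimum-length rule for
#' lncRNAs (noncoding transcripts shorter than `lnc_min_len` are not
#' lncRNAs by definition and are rejected).
#'
#' @param ann Annotation tibble (see [read_annotations()]).
#' @param lnc_min_len Minimum lncRNA locus length in bp (default 200 nt).
#' @return `ann`, invisibly, if valid; otherwise an error.
#' @export
validate_annotations <- function(ann, lnc_min_len = 200) {
  req <- c("transcript_id", "biotype", "chrom", "start", "end", "strand", "exons")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0) {
    stop("annotation table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(ann$transcript_id[duplicated(ann$transcript_id)])
  if (length(dup) > 0) {
    stop("duplicate transcript ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!all(ann$biotype %in% .BIOTYPES)) {
    bad <- unique(ann$biotype[!ann$biotype %in% .BIOTYPES])
    stop("unknown biotype value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  bad_span <- ann$start < 0 | ann$start >= ann$end
  if (any(bad_span)) {
    stop("invalid spans (need 0 <= start < end) for: ",
         paste(ann$transcript_id[bad_span], collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(ann))) {
    ex <- ann$exons[[i]]
    if (!is.matrix(ex) || ncol(ex) != 2 || nrow(ex) < 1) {
      stop("transcript ", ann$transcript_id[i],
           ": exons must be a two-column matrix with >= 1 row", call. = FALSE)
    }
    if (any(ex[, 1] >= ex[, 2])) {
      stop("transcript ", ann$transcript_id[i], ": empty or inverted exon",
           call. = FALSE)
    }
    if (ex[1, 1] < ann$start[i] || ex[nrow(ex), 2] > ann$end[i]) {
      stop("transcript ", ann$transcript_id[i],
           ": exons extend outside the transcript span", call. = FALSE)
    }
    if (nrow(ex) > 1) {
      if (is.unsorted(ex[, 1], strictly = TRUE) ||
          any(ex[-1, 1] < ex[-nrow(ex), 2])) {
        stop("transcript ", ann$transcript_id[i],
             ": exons must be sorted and non-overlapping", call. = FALSE)
      }
    }
  }
  short <- ann$biotype == "lncRNA" & (ann$end - ann$start) < lnc_min_len
  if (any(short)) {
    stop("lncRNA records shorter than ", lnc_min_len, " bp: ",
         paste(ann$transcript_id[short], collapse = ", "), call. = FALSE)
  }
  invisible(ann)
}

.annotation_tibble <- function(transcript_id, biotype, chrom, start, end,
                               strand, exons) {
  tibble::tibble(
    transcript_id = as.character(transcript_id),
    biotype = as.character(biotype),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    exons = exons
  )
}

# Cheap structural scan so malformed input is reported with a line number
# before it reaches the format parser.
.scan_fields <- function(path, min_fields, what) {
  lines <- readLines(path, warn = FALSE)
  skip <- grepl("^\\s*(#|track\\b|browser\\b)", lines) | !nzchar(trimws(lines))
  nf <- vapply(strsplit(lines, "[\t ]+"), length, integer(1))
  bad <- which(!skip & nf < min_fields)
  if (length(bad) > 0) {
    stop("malformed ", what, " line ", bad[1], " in '", path, "': expected >= ",
         min_fields, " fields, found ", nf[bad[1]], call. = FALSE)
  }
  invisible(NULL)
}

#' Read transcript annotations from BED12/BED6 or GTF
#'
#' Parses transcript annotations into the internal tibble representation:
#' one row per transcript with 0-based half-open `start`/`end`, strand, a
#' list-column `exons` of two-column interval matrices, and a `biotype` of
#' `"lncRNA"` or `"mRNA"`. GTF input (1-based inclusive) is converted on
#' read; BED is taken as is. BED carries no biotype, so `biotype` must be
#' supplied; for GTF the biotype is read from the attribute named by
#' `biotype_attr` and translated through `biotype_map` (set `biotype` to
#' override per file).
#'
#' @param path Input file.
#' @param format `"bed"` (BED6/BED12) or `"gtf"`.
#' @param biotype Optional biotype applied to every record (`"lncRNA"` or
#'   `"mRNA"`); required for BED input.
#' @param biotype_attr GTF attribute key holding the raw biotype
#'   (default `"gene_biotype"`).
#' @param biotype_map Named character vector translating raw attribute
#'   values to `"lncRNA"`/`"mRNA"`.
#' @param lnc_min_len Minimum lncRNA length in bp; shorter noncoding
#'   records are a validation error.
#' @return A validated annotation tibble.
#' @export
read_annotations <- function(path, format = c("bed", "gtf"), biotype = NULL,
                             biotype_attr = "gene_biotype",
                             biotype_map = default_biotype_map(),
                             lnc_min_len = 200) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ann <- switch(format,
    bed = .read_bed(path, biotype),
    gtf = .read_gtf(path, biotype, biotype_attr, biotype_map)
  )
  validate_annotations(ann, lnc_min_len = lnc_min_len)
  ann
}

.read_bed <- function(path, biotype) {
  if (is.null(biotype)) {
    stop("BED input carries no biotype; supply biotype = \"lncRNA\" or \"mRNA\"",
         call. = FALSE)
  }
  .scan_fields(path, 6, "BED")
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm) || anyNA(nm)) {
    stop("BED input must have a name (column 4) on every line", call. = FALSE)
  }
  if ("blocks" %in% names(S4Vectors::mcols(gr))) {
    bl <- S4Vectors::mcols(gr)$blocks
    exons <- lapply(seq_along(gr), function(i) {
      b <- bl[[i]]
      cbind(start = start0[i] + IRanges::start(b) - 1L,
            end = start0[i] + IRanges::end(b))
    })
  } else {
    exons <- lapply(seq_along(gr), function(i) {
      cbind(start = start0[i], end = end0[i])
    })
  }
  .annotation_tibble(
    transcript_id = as.character(nm),
    biotype = rep_len(biotype, length(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0, end = end0,
    strand = as.character(GenomicRanges::strand(gr)),
    exons = exons
  )
}

.read_gtf <- function(path, biotype, biotype_attr, biotype_map) {
  .scan_fields(path, 9, "GTF")
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  mc <- S4Vectors::mcols(gr)
  if (!"type" %in% names(mc)) stop("GTF lacks a feature type column", call. = FALSE)
  ex <- gr[as.character(mc$type) == "exon"]
  if (length(ex) == 0) stop("GTF contains no exon features", call. = FALSE)
  tid <- S4Vectors::mcols(ex)$transcript_id
  if (is.null(tid) || anyNA(tid)) {
    stop("GTF exon features must carry a transcript_id attribute", call. = FALSE)
  }
  tid <- as.character(tid)
  ids <- unique(tid)
  idx <- split(seq_along(ex), factor(tid, levels = ids))

  est <- GenomicRanges::start(ex) - 1L  # GTF 1-based inclusive -> 0-based half-open
  een <- GenomicRanges::end(ex)
  chr <- as.character(GenomicRanges::seqnames(ex))
  str <- as.character(GenomicRanges::strand(ex))

  if (is.null(biotype)) {
    raw_bt <- S4Vectors::mcols(ex)[[biotype_attr]]
    if (is.null(raw_bt)) {
      stop("GTF attribute '", biotype_attr, "' not found; supply biotype= or ",
           "another biotype_attr", call. = FALSE)
    }
    raw_bt <- as.character(raw_bt)
  }

  rows <- lapply(ids, function(id) {
    ii <- idx[[id]]
    if (length(unique(chr[ii])) != 1 || length(unique(str[ii])) != 1) {
      stop("transcript ", id, " spans multiple chromosomes or strands",
           call. = FALSE)
    }
    o <- order(est[ii])
    exm <- cbind(start = est[ii][o], end = een[ii][o])
    bt <- if (is.null(biotype)) {
      rb <- raw_bt[ii][1]
      if (is.na(rb) || !rb %in% names(biotype_map)) {
        stop("cannot map biotype value '", rb, "' for transcript ", id,
             "; extend biotype_map", call. = FALSE)
      }
      unname(biotype_map[[rb]])
    } else {
      biotype
    }
    list(id = id, bt = bt, chrom = chr[ii][1], strand = str[ii][1], exons = exm)
  })

  .annotation_tibble(
    transcript_id = vapply(rows, `[[`, character(1), "id"),
    biotype = vapply(rows, `[[`, character(1), "bt"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, function(r) r$exons[1, 1], numeric(1)),
    end = vapply(rows, function(r) r$exons[nrow(r$exons), 2], numeric(1)),
    strand = vapply(rows, `[[`, character(1), "strand"),
    exons = lapply(rows, `[[`, "exons")
  )
}

#' Write annotations as BED6
#'
#' Transcript spans only (no exon blocks). Coordinates round-trip
#' bit-exactly through [read_annotations()] because both sides use the
#' BED-native 0-based half-open convention.
#'
#' @param ann Annotation tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ann, path) {
  validate_annotations(ann)
  gr <- GenomicRanges::GRanges(
    ann$chrom,
    IRanges::IRanges(ann$start + 1L, ann$end),
    strand = ann$strand
  )
  S4Vectors::mcols(gr)$name <- ann$transcript_id
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write annotations as GTF exon features
#'
#' One `exon` feature per exon, carrying `gene_id`, `transcript_id` and
#' `gene_biotype` attributes, so the file round-trips through
#' [read_annotations()] with the default biotype map.
#'
#' @param ann Annotation tibble.
#' @param path Output file.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path, source = "lncprofiler") {
  validate_annotations(ann)
  n_ex <- vapply(ann$exons, nrow, integer(1))
  i <- rep(seq_len(nrow(ann)), n_ex)
  exm <- do.call(rbind, ann$exons)
  gr <- GenomicRanges::GRanges(
    ann$chrom[i],
    IRanges::IRanges(exm[, 1] + 1L, exm[, 2]),  # back to 1-based inclusive
    strand = ann$strand[i]
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = source,
    type = "exon",
    gene_id = ann$transcript_id[i],
    transcript_id = ann$transcript_id[i],
    gene_biotype = ann$biotype[i]
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
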