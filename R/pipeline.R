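#' Default pipeline configuration
#'
#' Flat key/value configuration for [run_pipeline()]. Thresholds default to
#' the published criteria: fold-change >= 5, p <= 0.05, bidirectional
#' distance < 1 kb, cis window 10 kb, minimum lncRNA length 200 nt.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    # inputs; either generate = TRUE or matrix/meta (+ lnc/genes) paths
    generate = FALSE,
    seed = 1L,
    matrix = NULL, meta = NULL, flags = NULL,
    lnc = NULL, genes = NULL,
    annotation_format = "gtf",
    out = NULL,
    # thresholds (published defaults)
    fc = 5, p = 0.05,
    bidirectional_gap = 1000, cis_window = 10000, lnc_min_len = 200,
    # background flag model (log2 scale)
    bg_mu = 6, bg_sigma = 1, k_present = 3, k_marginal = 2,
    # focal tissue for summaries and rounding of report percentages
    tissue = "testis", decimals = 1,
    # generator sizes when generate = TRUE
    n_transcripts = 2000, n_genes = 30, n_lncs = 60
  )
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are
#' coerced to numeric or logical where possible. Unknown keys are an
#' error, so typos do not silently fall back to defaults.
#'
#' @param path Configuration file.
#' @return Named list merging the file over [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (!key %in% names(cfg)) stop("unknown config key: ", key, call. = FALSE)
    if (toupper(val) %in% c("TRUE", "FALSE")) {
      val <- as.logical(val)
    } else if (!is.na(suppressWarnings(as.numeric(val)))) {
      val <- as.numeric(val)
    }
    cfg[[key]] <- val
  }
  cfg
}

.write_tsv <- function(df, path, schema = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(schema)) writeLines(paste0("# columns: ", schema), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full profiling pipeline
#'
#' Orchestrates flags -> specificity calls -> subtype classification ->
#' cis-target search -> summaries, either on files named in the
#' configuration or on freshly generated synthetic data (`generate =
#' TRUE`). Writes `calls.tsv`, `subtypes.tsv`, `cis.tsv`,
#' `chrom_summary.tsv`, `subtype_proportions.tsv` and a machine-readable
#' `report.json` (plus `truth.json` and the generated inputs when
#' generating) under `config$out`, and returns the report. Rerunning with
#' the same configuration reproduces the report exactly.
#'
#' @param config Named list (see [default_config()]) or a path accepted by
#'   [read_config()].
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- default_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(config)] <- config
  if (is.null(cfg$out)) stop("config$out (output directory) is required", call. = FALSE)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  bg <- background_model(cfg$bg_mu, cfg$bg_sigma, cfg$k_present, cfg$k_marginal)

  if (isTRUE(cfg$generate)) {
    gg <- generate_genome(cfg$seed, n_genes = cfg$n_genes, n_lncs = cfg$n_lncs)
    ann <- gg$annotations
    ge <- generate_expression(
      cfg$seed, n_transcripts = cfg$n_transcripts, bg = bg,
      transcript_ids = c(ann$transcript_id[ann$biotype == "lncRNA"],
                         sprintf("t%05d", seq_len(cfg$n_transcripts -
                                                    sum(ann$biotype == "lncRNA")))))
    m <- ge$matrix
    write_gtf(ann[ann$biotype == "lncRNA", ], file.path(cfg$out, "lnc.gtf"))
    write_gtf(ann[ann$biotype == "mRNA", ], file.path(cfg$out, "genes.gtf"))
    write_truth(c(gg$truth["subtype_labels"], gg$truth["cis_pairs"],
                  ge$truth),
                file.path(cfg$out, "truth.json"))
    .write_tsv(data.frame(transcript_id = rownames(m$values), m$values,
                          check.names = FALSE),
               file.path(cfg$out, "matrix.tsv"),
               "transcript_id, then one normalized linear intensity per sample")
    .write_tsv(m$samples, file.path(cfg$out, "meta.tsv"),
               "sample_id, tissue, replicate, source_kind")
  } else {
    if (is.null(cfg$matrix) || is.null(cfg$meta)) {
      stop("config must name matrix and meta files (or set generate = TRUE)",
           call. = FALSE)
    }
    m <- read_matrix(cfg$matrix, cfg$meta, cfg$flags)
    ann <- NULL
    if (!is.null(cfg$lnc)) {
      lnc_bt <- if (cfg$annotation_format == "bed") "lncRNA" else NULL
      gene_bt <- if (cfg$annotation_format == "bed") "mRNA" else NULL
      ann <- rbind(
        read_annotations(cfg$lnc, cfg$annotation_format, biotype = lnc_bt,
                         lnc_min_len = cfg$lnc_min_len),
        read_annotations(cfg$genes, cfg$annotation_format, biotype = gene_bt,
                         lnc_min_len = cfg$lnc_min_len)
      )
    }
  }

  if (is.null(m$flags)) m <- compute_flags(m, bg)
  calls <- call_specific(m, fc_threshold = cfg$fc, p_threshold = cfg$p)
  .write_tsv(calls, file.path(cfg$out, "calls.tsv"),
             "transcript_id, target_tissue, flag_rule_passed, min_fold_change, p_value, is_specific")

  report <- list(
    seed = cfg$seed,
    thresholds = list(fc = cfg$fc, p = cfg$p,
                      bidirectional_gap = cfg$bidirectional_gap,
                      cis_window = cfg$cis_window),
    n_transcripts = nrow(m$values),
    n_samples = ncol(m$values),
    specific_per_tissue = as.list(stats::setNames(
      specific_counts(calls)$n_specific, specific_counts(calls)$tissue))
  )

  if (!is.null(ann)) {
    lncs <- ann[ann$biotype == "lncRNA", , drop = FALSE]
    genes <- ann[ann$biotype == "mRNA", , drop = FALSE]
    labels <- classify_lncrnas(lncs, genes,
                               bidirectional_gap = cfg$bidirectional_gap)
    .write_tsv(labels, file.path(cfg$out, "subtypes.tsv"),
               "transcript_id, subtype, partner_gene_id, evidence, overlap_bp, gap_bp")
    props <- subtype_proportions(labels, cfg$decimals)
    .write_tsv(props, file.path(cfg$out, "subtype_proportions.tsv"),
               "subtype, n, pct")
    linc_ids <- labels$transcript_id[labels$subtype == "intergenic"]
    lincs <- lncs[lncs$transcript_id %in% linc_ids, , drop = FALSE]
    pairs <- find_nearby_genes(lincs, genes, window = cfg$cis_window,
                               labels = labels)
    .write_tsv(pairs, file.path(cfg$out, "cis.tsv"),
               "lincRNA_id, gene_id, signed_distance, orientation")
    annotated <- intersect(rownames(m$values), ann$transcript_id)
    chrom <- chrom_distribution(
      calls[calls$transcript_id %in% ann$transcript_id, , drop = FALSE],
      ann, tissue = cfg$tissue)
    .write_tsv(chrom, file.path(cfg$out, "chrom_summary.tsv"),
               paste("chrom, n_total_lnc, n_specific_lnc, n_total_mrna,",
                     "n_specific_mrna, ratio_lnc, ratio_mrna,",
                     "degenerate_lnc, degenerate_mrna"))
    report$subtype_counts <- as.list(stats::setNames(props$n, props$subtype))
    report$subtype_pct <- as.list(stats::setNames(props$pct, props$subtype))
    report$cis <- cis_summary(pairs, n_lincs = length(linc_ids),
                              decimals = cfg$decimals)
    report$n_annotated_transcripts <- length(annotated)
  }

  jsonlite::write_json(report, file.path(cfg$out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
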