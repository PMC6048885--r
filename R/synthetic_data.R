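#' Synthetic data with planted ground truth
#'
#' The generators below emulate the study design the pipeline targets —
#' five tissues with three replicates each on a log-normal intensity scale,
#' and a gene/lncRNA geometry instantiating every positional subtype — and
#' emit the planted labels alongside, so recovery can be scored without any
#' external data. Same seed, same output, bit for bit.
#'
#' @name synthetic_data
NULL

.apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic genome with planted subtype geometries
#'
#' Places protein-coding genes on evenly spaced, well-separated slots
#' (one gene per `slot_bp`), then constructs each lncRNA so that it
#' satisfies exactly one positional subtype definition relative to its
#' host gene: exonic lncRNAs overlap an exon, intronic lncRNAs sit
#' strictly inside an intron, bidirectional lncRNAs lie 1-999 bp from the
#' gene locus, and intergenic lncRNAs at least 2 kb away (the extra
#' margin over the 1-kb rule keeps planted labels unambiguous under any
#' boundary convention). Intergenic lncRNAs placed within the
#' `cis_window` of their host gene are recorded as planted cis pairs.
#'
#' @param seed Integer seed; outputs are fully determined by it.
#' @param n_chroms Number of chromosomes (genes assigned round-robin).
#' @param n_genes Number of protein-coding genes (1-5 exons each).
#' @param n_lncs Number of lncRNAs.
#' @param subtype_mix Named fractions over the six subtypes, summing to 1.
#' @param cis_window Window used to record planted cis pairs (default
#'   10000).
#' @param slot_bp Genomic slot reserved per gene (default 1e5); must be
#'   large enough to isolate neighboring geometries.
#' @return A list with `annotations` (genes then lncRNAs, one validated
#'   tibble) and `truth` (list with `subtype_labels`, `cis_pairs`,
#'   `seed`).
#' @export
generate_genome <- function(seed, n_chroms = 3, n_genes = 30, n_lncs = 60,
                            subtype_mix = stats::setNames(rep(1 / 6, 6), c(
                              "exonic_sense", "exonic_antisense",
                              "intronic_sense", "intronic_antisense",
                              "bidirectional", "intergenic")),
                            cis_window = 10000, slot_bp = 100000) {
  stopifnot(n_chroms >= 1, n_genes >= 0, n_lncs >= 0)
  if (slot_bp < 60000) {
    stop("slot_bp too small to isolate planted geometries; ",
         "use longer chromosomes (slot_bp >= 60000)", call. = FALSE)
  }
  if (!all(names(subtype_mix) %in% .SUBTYPES) || is.null(names(subtype_mix))) {
    stop("subtype_mix must be named by the six subtypes", call. = FALSE)
  }
  if (abs(sum(subtype_mix) - 1) > 1e-8) {
    stop("subtype_mix fractions must sum to 1", call. = FALSE)
  }
  withr::with_seed(seed, {
    counts <- .apportion(n_lncs, subtype_mix)
    names(counts) <- names(subtype_mix)
    wants_host <- sum(counts[setdiff(names(counts), "intergenic")]) > 0
    if (n_genes == 0 && n_lncs > 0) {
      if (wants_host || counts[["intergenic"]] < n_lncs) {
        warning("no genes generated: all lncRNAs are intergenic regardless ",
                "of subtype_mix", call. = FALSE)
      }
      counts[] <- 0L
      counts["intergenic"] <- as.integer(n_lncs)
    }

    genes <- NULL
    if (n_genes > 0) {
      n_ex <- sample(1:5, n_genes, replace = TRUE)
      if (sum(counts[c("intronic_sense", "intronic_antisense")]) > 0 &&
          !any(n_ex >= 2)) {
        n_ex[1] <- 3L  # guarantee an intron host
      }
      chrom_i <- rep_len(seq_len(n_chroms), n_genes)
      slot_i <- unlist(lapply(seq_len(n_chroms),
                              function(c) seq_len(sum(chrom_i == c)))) - 1L
      slot_i <- slot_i[order(order(chrom_i))]  # slot index within chromosome
      # deterministic layout: gene g sits slot_bp*slot + 20 kb into its slot
      exon_len <- 300L
      intron_len <- 4000L
      g_start <- slot_i * slot_bp + 20000L
      exons <- lapply(seq_len(n_genes), function(g) {
        st <- g_start[g] + (seq_len(n_ex[g]) - 1L) * (exon_len + intron_len)
        cbind(start = st, end = st + exon_len)
      })
      genes <- .annotation_tibble(
        transcript_id = sprintf("gene%04d", seq_len(n_genes)),
        biotype = "mRNA",
        chrom = paste0("chr", chrom_i),
        start = g_start,
        end = vapply(exons, function(e) e[nrow(e), 2], numeric(1)),
        strand = sample(c("+", "-"), n_genes, replace = TRUE),
        exons = exons
      )
    }

    subtype_of <- rep(names(counts), counts)
    if (length(subtype_of) > 0) subtype_of <- sample(subtype_of)
    lnc_rows <- vector("list", length(subtype_of))
    cis_pairs <- list()
    multi_exon <- if (n_genes > 0) {
      which(vapply(genes$exons, nrow, integer(1)) >= 2)
    } else {
      integer(0)
    }
    for (i in seq_along(subtype_of)) {
      st <- subtype_of[i]
      id <- sprintf("lnc%04d", i)
      if (n_genes == 0) {
        chrom <- "chr1"
        start <- 20000L + (i - 1L) * 50000L
        len <- sample(300:1500, 1)
        row <- list(chrom = chrom, start = start, end = start + len,
                    strand = sample(c("+", "-"), 1))
      } else {
        host <- if (st %in% c("intronic_sense", "intronic_antisense")) {
          multi_exon[sample.int(length(multi_exon), 1)]
        } else {
          sample.int(n_genes, 1)
        }
        hx <- genes$exons[[host]]
        hstrand <- genes$strand[host]
        row <- switch(st,
          exonic_sense = ,
          exonic_antisense = {
            e <- sample.int(nrow(hx), 1)
            off <- sample(0:100, 1)
            start <- max(0L, hx[e, 1] - off)
            len <- sample(300:800, 1)
            strand <- if (st == "exonic_sense") hstrand else setdiff(c("+", "-"), hstrand)
            list(chrom = genes$chrom[host], start = start, end = start + len,
                 strand = strand)
          },
          intronic_sense = ,
          intronic_antisense = {
            intr <- introns_of(hx)
            j <- sample.int(nrow(intr), 1)
            start <- intr[j, 1] + sample(200:1000, 1)
            max_len <- intr[j, 2] - 200L - start
            len <- sample(300:min(1500L, max_len), 1)
            strand <- if (st == "intronic_sense") hstrand else setdiff(c("+", "-"), hstrand)
            list(chrom = genes$chrom[host], start = start, end = start + len,
                 strand = strand)
          },
          bidirectional = {
            g <- sample(1:999, 1)
            start <- genes$end[host] + g
            len <- sample(300:1000, 1)
            list(chrom = genes$chrom[host], start = start, end = start + len,
                 strand = sample(c("+", "-"), 1))
          },
          intergenic = {
            g <- sample(2000:30000, 1)
            start <- genes$end[host] + g
            len <- sample(300:1500, 1)
            list(chrom = genes$chrom[host], start = start, end = start + len,
                 strand = sample(c("+", "-"), 1), host_gap = g,
                 host_id = genes$transcript_id[host])
          }
        )
        if (st == "intergenic" && row$host_gap <= cis_window - 1) {
          cis_pairs[[length(cis_pairs) + 1]] <- c(id, row$host_id)
        }
        row$host_gap <- NULL
        row$host_id <- NULL
      }
      lnc_rows[[i]] <- c(list(id = id, subtype = st), row)
    }

    lncs <- NULL
    if (length(lnc_rows) > 0) {
      lncs <- .annotation_tibble(
        transcript_id = vapply(lnc_rows, `[[`, character(1), "id"),
        biotype = "lncRNA",
        chrom = vapply(lnc_rows, `[[`, character(1), "chrom"),
        start = vapply(lnc_rows, function(r) as.numeric(r$start), numeric(1)),
        end = vapply(lnc_rows, function(r) as.numeric(r$end), numeric(1)),
        strand = vapply(lnc_rows, `[[`, character(1), "strand"),
        exons = lapply(lnc_rows, function(r) {
          cbind(start = as.numeric(r$start), end = as.numeric(r$end))
        })
      )
    }
    annotations <- do.call(rbind, Filter(Negate(is.null), list(genes, lncs)))
    validate_annotations(annotations)

    cis_df <- if (length(cis_pairs) > 0) {
      m <- do.call(rbind, cis_pairs)
      tibble::tibble(lincRNA_id = m[, 1], gene_id = m[, 2])
    } else {
      tibble::tibble(lincRNA_id = character(0), gene_id = character(0))
    }
    truth <- list(
      subtype_labels = stats::setNames(
        vapply(lnc_rows, `[[`, character(1), "subtype"),
        vapply(lnc_rows, `[[`, character(1), "id")),
      cis_pairs = cis_df,
      seed = as.integer(seed)
    )
    list(annotations = annotations, truth = truth)
  })
}

#' Generate an expression matrix with planted tissue-specific transcripts
#'
#' Emulates the multi-tissue design (default: brain, heart, kidney, liver,
#' testis with three replicates each) on a log-normal intensity model.
#' Non-specific transcripts draw log2 intensities at the background mean
#' (flagging absent) except for a configurable ubiquitous fraction
#' expressed well above the present threshold in every tissue. A planted
#' tissue-specific transcript draws `mu_bg + log2(fold)` in its target
#' tissue and background level elsewhere, so its expected linear
#' fold-change equals `fold` exactly. Replicate noise is additive Gaussian
#' on the log2 scale.
#'
#' @param seed Integer seed.
#' @param tissues Tissue labels.
#' @param replicates Replicates per tissue (default 3).
#' @param n_transcripts Number of transcripts.
#' @param planted Named fractions of transcripts planted specific per
#'   tissue (names must be tissues; fractions sum to <= 1).
#' @param fold Planted linear fold-change (> 1; default 20).
#' @param bg A [background_model()] (default mu 6, sigma 1, log2 scale).
#' @param noise_sd Replicate noise SD in log2 units (default 0.3).
#' @param ubiquitous_frac Fraction of non-planted transcripts expressed in
#'   every tissue (default 0.3).
#' @param transcript_ids Optional ids (default `t00001`, ...).
#' @return A list with `matrix` (an [expr_matrix()], flags not yet
#'   computed) and `truth` (list with `specific_transcripts` per tissue,
#'   `ubiquitous`, `planted_fold`, `noise_sd`, `seed`).
#' @export
generate_expression <- function(seed,
                                tissues = c("brain", "heart", "kidney",
                                            "liver", "testis"),
                                replicates = 3, n_transcripts = 2000,
                                planted = c(testis = 0.025), fold = 20,
                                bg = background_model(6, 1), noise_sd = 0.3,
                                ubiquitous_frac = 0.3,
                                transcript_ids = NULL) {
  if (fold <= 1) stop("fold must be > 1", call. = FALSE)
  if (replicates < 2) stop("need >= 2 replicates per tissue", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!all(names(planted) %in% tissues)) {
    stop("planted names must be tissues", call. = FALSE)
  }
  if (sum(planted) > 1) stop("planted fractions must sum to <= 1", call. = FALSE)
  if (is.null(transcript_ids)) {
    transcript_ids <- sprintf("t%05d", seq_len(n_transcripts))
  }
  stopifnot(length(transcript_ids) == n_transcripts)
  withr::with_seed(seed, {
    samples <- tibble::tibble(
      sample_id = paste0(rep(tissues, each = replicates), "_r",
                         rep(seq_len(replicates), length(tissues))),
      tissue = rep(tissues, each = replicates),
      replicate = rep(seq_len(replicates), length(tissues)),
      source_kind = "tissue"
    )
    n_cells <- n_transcripts * nrow(samples)
    base <- matrix(bg$mu, nrow = n_transcripts, ncol = nrow(samples),
                   dimnames = list(transcript_ids, samples$sample_id))

    pool <- seq_len(n_transcripts)
    specific <- list()
    for (t in names(planted)) {
      k <- round(planted[[t]] * n_transcripts)
      pick <- if (k > 0) sort(sample(pool, k)) else integer(0)
      specific[[t]] <- transcript_ids[pick]
      pool <- setdiff(pool, pick)
      base[pick, samples$tissue == t] <- bg$mu + log2(fold)
    }
    n_ubiq <- round(ubiquitous_frac * length(pool))
    ubiq <- if (n_ubiq > 0) sort(sample(pool, n_ubiq)) else integer(0)
    base[ubiq, ] <- bg$mu + bg$k_present * bg$sigma + 2

    noise <- if (noise_sd > 0) {
      matrix(stats::rnorm(n_cells, 0, noise_sd), nrow = n_transcripts)
    } else {
      0
    }
    values <- 2^(base + noise)
    truth <- list(
      specific_transcripts = specific,
      ubiquitous = transcript_ids[ubiq],
      planted_fold = fold,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    )
    list(matrix = expr_matrix(values, samples), truth = truth)
  })
}

#' Serialize planted truth to JSON
#' @param truth Truth list from [generate_genome()] or
#'   [generate_expression()].
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  if (!is.null(truth$subtype_labels)) {
    truth$subtype_labels <- as.list(truth$subtype_labels)  # keep names in JSON
  }
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read planted truth from JSON
#' @param path JSON file written by [write_truth()].
#' @return The truth list, with `cis_pairs` restored as a tibble and
#'   vector fields as named character vectors.
#' @export
read_truth <- function(path) {
  truth <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(truth$subtype_labels)) {
    truth$subtype_labels <- unlist(truth$subtype_labels)
  }
  if (!is.null(truth$cis_pairs)) {
    cp <- truth$cis_pairs
    if (length(cp) == 0 || is.null(dim(cp))) {
      truth$cis_pairs <- tibble::tibble(lincRNA_id = character(0),
                                        gene_id = character(0))
    } else {
      truth$cis_pairs <- tibble::as_tibble(cp)
    }
  }
  if (!is.null(truth$specific_transcripts)) {
    truth$specific_transcripts <- lapply(truth$specific_transcripts,
                                         as.character)
  }
  if (!is.null(truth$ubiquitous)) truth$ubiquitous <- as.character(truth$ubiquitous)
  if (!is.null(truth$seed)) truth$seed <- as.integer(truth$seed)
  truth
}
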