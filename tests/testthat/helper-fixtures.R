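# Small builders used across the suite; everything is constructed in code.

ann_row <- function(id, biotype, chrom, start, end, strand, exons = NULL) {
  if (is.null(exons)) exons <- cbind(start = start, end = end)
  tibble::tibble(transcript_id = id, biotype = biotype, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, exons = list(exons))
}

make_gene <- function(id, chrom, exon_starts, exon_ends, strand = "+") {
  ann_row(id, "mRNA", chrom, min(exon_starts), max(exon_ends), strand,
          cbind(start = exon_starts, end = exon_ends))
}

make_lnc <- function(id, chrom, start, end, strand = "+") {
  ann_row(id, "lncRNA", chrom, start, end, strand)
}

DEFAULT_TISSUES <- c("brain", "heart", "kidney", "liver", "testis")

# Expression matrix from per-transcript log2 levels. Each element of
# `log2_rows` is either one level per tissue (replicates identical) or one
# level per sample.
make_matrix <- function(log2_rows, tissues = DEFAULT_TISSUES, reps = 3) {
  n_s <- length(tissues) * reps
  vals <- t(vapply(log2_rows, function(v) {
    if (length(v) == length(tissues)) rep(v, each = reps) else rep_len(v, n_s)
  }, numeric(n_s)))
  rownames(vals) <- names(log2_rows)
  colnames(vals) <- paste0(rep(tissues, each = reps), "_r",
                           rep(seq_len(reps), length(tissues)))
  samples <- tibble::tibble(
    sample_id = colnames(vals),
    tissue = rep(tissues, each = reps),
    replicate = rep(seq_len(reps), length(tissues))
  )
  expr_matrix(2^vals, samples)
}

# As make_matrix, but rows are linear intensities taken verbatim (no
# log2/2^ round trip, so exact group means survive).
make_matrix_linear <- function(rows, tissues = DEFAULT_TISSUES, reps = 3) {
  n_s <- length(tissues) * reps
  vals <- t(vapply(rows, function(v) {
    if (length(v) == length(tissues)) rep(v, each = reps) else rep_len(v, n_s)
  }, numeric(n_s)))
  rownames(vals) <- names(rows)
  colnames(vals) <- paste0(rep(tissues, each = reps), "_r",
                           rep(seq_len(reps), length(tissues)))
  samples <- tibble::tibble(
    sample_id = colnames(vals),
    tissue = rep(tissues, each = reps),
    replicate = rep(seq_len(reps), length(tissues))
  )
  expr_matrix(vals, samples)
}

# Attach hand-written flags (one "P"/"M"/"A" per tissue per transcript,
# or one per sample) to an expr_matrix.
set_flags <- function(m, flag_rows) {
  tiss <- m$samples$tissue
  fl <- t(vapply(flag_rows, function(v) {
    if (length(v) == length(unique(tiss))) {
      v[match(tiss, unique(tiss))]
    } else {
      rep_len(v, ncol(m$values))
    }
  }, character(ncol(m$values))))
  dimnames(fl) <- dimnames(m$values)
  m$flags <- fl
  m
}

# Messy random gene/lncRNA geometries (unlike the planted generator, these
# are unconstrained so every positional relation can arise by chance).
random_genome <- function(seed, n_genes = 10, n_lncs = 15, n_chroms = 2,
                          chrom_len = 30000) {
  withr::with_seed(seed, {
    genes <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
      n_ex <- sample(1:3, 1)
      pos <- sample(0:(chrom_len - 5000), 1)
      starts <- ends <- integer(n_ex)
      for (e in seq_len(n_ex)) {
        starts[e] <- pos
        ends[e] <- pos + sample(100:400, 1)
        pos <- ends[e] + sample(50:1500, 1)
      }
      make_gene(sprintf("g%03d", g), paste0("chr", sample(n_chroms, 1)),
                starts, ends, sample(c("+", "-"), 1))
    }))
    lncs <- do.call(rbind, lapply(seq_len(n_lncs), function(l) {
      start <- sample(0:(chrom_len - 2100), 1)
      make_lnc(sprintf("l%03d", l), paste0("chr", sample(n_chroms, 1)),
               start, start + sample(200:2000, 1), sample(c("+", "-"), 1))
    }))
    list(genes = genes, lncs = lncs)
  })
}
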