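# Independent brute-force reference implementations. These deliberately
# avoid the package's interval helpers and vectorized paths: everything is
# spelled out with min/max arithmetic and exhaustive loops.

.o_overlap <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))
.o_gap <- function(a1, a2, b1, b2) max(0, max(a1, b1) - min(a2, b2))

# Exhaustive positional classification of one lncRNA: visits every gene,
# every exon and every intron.
oracle_classify_one <- function(lnc, genes, bidirectional_gap = 1000) {
  exov <- c()
  inov <- c()
  gaps <- c()
  gid <- c()
  gstr <- c()
  for (g in seq_len(nrow(genes))) {
    if (genes$chrom[g] != lnc$chrom) next
    ex <- genes$exons[[g]]
    eo <- 0
    for (e in seq_len(nrow(ex))) {
      eo <- eo + .o_overlap(lnc$start, lnc$end, ex[e, 1], ex[e, 2])
    }
    io <- 0
    if (nrow(ex) > 1) {
      for (k in seq_len(nrow(ex) - 1)) {
        io <- io + .o_overlap(lnc$start, lnc$end, ex[k, 2], ex[k + 1, 1])
      }
    }
    exov <- c(exov, eo)
    inov <- c(inov, io)
    gaps <- c(gaps, .o_gap(lnc$start, lnc$end, genes$start[g], genes$end[g]))
    gid <- c(gid, genes$transcript_id[g])
    gstr <- c(gstr, genes$strand[g])
  }
  if (length(gid) == 0) return("intergenic")
  sense <- function(j) if (gstr[j] == lnc$strand) "sense" else "antisense"
  if (any(exov > 0)) {
    cand <- which(exov > 0)
    j <- cand[order(-exov[cand], gaps[cand], gid[cand])][1]
    return(paste0("exonic_", sense(j)))
  }
  if (any(inov > 0)) {
    cand <- which(inov > 0)
    j <- cand[order(-inov[cand], gaps[cand], gid[cand])][1]
    return(paste0("intronic_", sense(j)))
  }
  if (min(gaps) < bidirectional_gap) return("bidirectional")
  "intergenic"
}

oracle_classify <- function(lncs, genes, bidirectional_gap = 1000) {
  vapply(seq_len(nrow(lncs)),
         function(i) oracle_classify_one(lncs[i, ], genes, bidirectional_gap),
         character(1))
}

# All-pairs window scan for cis targets of intergenic lncRNAs.
oracle_cis_pairs <- function(lincs, genes, window = 10000) {
  out <- character(0)
  for (i in seq_len(nrow(lincs))) {
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] != lincs$chrom[i]) next
      gp <- .o_gap(lincs$start[i], lincs$end[i], genes$start[g], genes$end[g])
      ov <- .o_overlap(lincs$start[i], lincs$end[i],
                       genes$start[g], genes$end[g])
      if (ov > 0 || gp < window) {
        out <- c(out, paste(lincs$transcript_id[i],
                            genes$transcript_id[g]))
      }
    }
  }
  sort(out)
}

# Naive per-transcript re-evaluation of the specificity rule, with the
# p-value taken from stats::t.test as the independent route.
oracle_specific <- function(m, fc = 5, p = 0.05) {
  tiss <- unique(m$samples$tissue)
  out <- list()
  for (i in seq_len(nrow(m$values))) {
    for (t in tiss) {
      target <- m$samples$tissue == t
      f <- m$flags[i, ]
      rule <- all(f[target] %in% c("P", "M")) && all(f[!target] == "A")
      denoms <- vapply(setdiff(tiss, t), function(o) {
        mean(m$values[i, m$samples$tissue == o])
      }, numeric(1))
      fcv <- mean(m$values[i, target]) / max(denoms)
      x <- log2(m$values[i, target])
      y <- log2(m$values[i, !target])
      pv <- tryCatch(
        stats::t.test(x, y, var.equal = TRUE)$p.value,
        error = function(e) if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
      )
      out[[length(out) + 1]] <- data.frame(
        transcript_id = rownames(m$values)[i], target_tissue = t,
        is_specific = rule && fcv >= fc && pv <= p
      )
    }
  }
  do.call(rbind, out)
}
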