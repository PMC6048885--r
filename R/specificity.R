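#' Tissue-specificity calling
#'
#' A transcript is called specific to a tissue when three criteria hold
#' jointly: (1) it is flagged P or M in every replicate of that tissue and
#' A in every replicate of every other tissue; (2) its fold-change relative
#' to the other tissues is at least `fc_threshold` (default 5); (3) a
#' two-sided equal-variance Student's t-test of its log2 intensities,
#' target replicates versus all other-tissue replicates pooled, gives
#' `p <= p_threshold` (default 0.05). The flag criterion alone guarantees
#' that no transcript can be specific to two tissues.
#'
#' @name specificity
NULL

.tissue_cols <- function(m) {
  split(seq_len(ncol(m$values)), factor(m$samples$tissue,
                                        levels = unique(m$samples$tissue)))
}

.row_var <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

.transcript_index <- function(m, transcript) {
  i <- match(transcript, rownames(m$values))
  if (is.na(i)) stop("unknown transcript: ", transcript, call. = FALSE)
  i
}

.tissue_check <- function(m, tissue) {
  if (!tissue %in% m$samples$tissue) stop("unknown tissue: ", tissue, call. = FALSE)
  invisible(tissue)
}

#' Replicate-consistency flag rule for one transcript
#'
#' `TRUE` iff every replicate of `tissue` is flagged P or M for the
#' transcript and every replicate of every other tissue is flagged A.
#'
#' @param m An [expr_matrix()] with flags populated.
#' @param transcript Transcript id.
#' @param tissue Candidate tissue.
#' @return Logical scalar.
#' @export
flag_rule <- function(m, transcript, tissue) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(m$flags)) stop("flags not populated; run compute_flags()", call. = FALSE)
  i <- .transcript_index(m, transcript)
  .tissue_check(m, tissue)
  target <- m$samples$tissue == tissue
  f <- m$flags[i, ]
  all(f[target] %in% c("P", "M")) && all(f[!target] == "A")
}

# transcripts x tissues logical matrix of the flag rule
.flag_rule_matrix <- function(m) {
  cols <- .tissue_cols(m)
  pm <- m$flags == "P" | m$flags == "M"
  aa <- m$flags == "A"
  ok_pm <- vapply(cols, function(cc) rowSums(pm[, cc, drop = FALSE]) == length(cc),
                  logical(nrow(m$values)))
  all_a <- vapply(cols, function(cc) rowSums(aa[, cc, drop = FALSE]) == length(cc),
                  logical(nrow(m$values)))
  ok_pm <- matrix(ok_pm, nrow = nrow(m$values), dimnames = list(NULL, names(cols)))
  all_a <- matrix(all_a, nrow = nrow(m$values), dimnames = list(NULL, names(cols)))
  k <- length(cols)
  out <- ok_pm
  for (j in seq_len(k)) {
    out[, j] <- ok_pm[, j] &
      rowSums(all_a[, -j, drop = FALSE]) == (k - 1)
  }
  out
}

# transcripts x tissues matrix of linear-scale group means
.group_means <- function(m) {
  cols <- .tissue_cols(m)
  out <- vapply(cols, function(cc) rowMeans(m$values[, cc, drop = FALSE]),
                numeric(nrow(m$values)))
  matrix(out, nrow = nrow(m$values),
         dimnames = list(rownames(m$values), names(cols)))
}

#' Fold-change of one transcript in one tissue relative to the others
#'
#' Linear-scale ratio of tissue means. The default `"min_pairwise"` method
#' returns the minimum ratio of the target-tissue mean over each other
#' tissue's mean, so a threshold of 5 guarantees at least five-fold
#' enrichment against every other tissue. The `"pooled"` alternative
#' divides by the mean over all other-tissue samples pooled.
#'
#' @inheritParams flag_rule
#' @param method `"min_pairwise"` (default) or `"pooled"`.
#' @return Positive numeric fold-change.
#' @export
fold_change <- function(m, transcript, tissue,
                        method = c("min_pairwise", "pooled")) {
  stopifnot(inherits(m, "expr_matrix"))
  method <- match.arg(method)
  i <- .transcript_index(m, transcript)
  .tissue_check(m, tissue)
  target <- m$samples$tissue == tissue
  num <- mean(m$values[i, target])
  if (method == "min_pairwise") {
    others <- setdiff(unique(m$samples$tissue), tissue)
    denoms <- vapply(others,
                     function(t) mean(m$values[i, m$samples$tissue == t]),
                     numeric(1))
    num / max(denoms)
  } else {
    num / mean(m$values[i, !target])
  }
}

.fold_change_matrix <- function(m, method = "min_pairwise") {
  gm <- .group_means(m)
  k <- ncol(gm)
  out <- gm
  for (j in seq_len(k)) {
    if (method == "min_pairwise") {
      denom <- apply(gm[, -j, drop = FALSE], 1, max)
    } else {
      other <- m$samples$tissue != colnames(gm)[j]
      denom <- rowMeans(m$values[, other, drop = FALSE])
    }
    out[, j] <- gm[, j] / denom
  }
  out
}

.pooled_t_p <- function(mx, vx, n1, my, vy, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * vx + (n2 - 1) * vy) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- ifelse(se > 0,
              2 * stats::pt(-abs((mx - my) / ifelse(se > 0, se, 1)), df),
              ifelse(mx == my, 1, 0))
  p
}

#' Student's t-test of one transcript in one tissue versus the rest
#'
#' Two-sided, equal-variance (pooled) two-sample t-test on log2
#' intensities: the target tissue's replicates against all other-tissue
#' replicates pooled. Degenerate zero-variance cases follow the
#' convention p = 1 when the group means are equal and p = 0 otherwise.
#'
#' @inheritParams flag_rule
#' @return A p-value in `[0, 1]`.
#' @export
tissue_t_test <- function(m, transcript, tissue) {
  stopifnot(inherits(m, "expr_matrix"))
  i <- .transcript_index(m, transcript)
  .tissue_check(m, tissue)
  target <- m$samples$tissue == tissue
  x <- log2(m$values[i, target])
  y <- log2(m$values[i, !target])
  if (length(x) < 2 || length(y) < 2) {
    stop("need >= 2 replicates in the target tissue and >= 2 pooled samples",
         call. = FALSE)
  }
  .pooled_t_p(mean(x), stats::var(x), length(x),
              mean(y), stats::var(y), length(y))
}

# transcripts x tissues matrix of pooled-t p-values on log2 intensities
.t_test_matrix <- function(m) {
  lx <- log2(m$values)
  cols <- .tissue_cols(m)
  out <- matrix(NA_real_, nrow = nrow(lx), ncol = length(cols),
                dimnames = list(rownames(lx), names(cols)))
  for (j in seq_along(cols)) {
    cc <- cols[[j]]
    oc <- setdiff(seq_len(ncol(lx)), cc)
    if (length(cc) < 2 || length(oc) < 2) {
      stop("each tissue needs >= 2 replicates and >= 2 pooled other samples",
           call. = FALSE)
    }
    x <- lx[, cc, drop = FALSE]
    y <- lx[, oc, drop = FALSE]
    out[, j] <- .pooled_t_p(rowMeans(x), .row_var(x), length(cc),
                            rowMeans(y), .row_var(y), length(oc))
  }
  out
}

#' Call tissue-specific transcripts
#'
#' Evaluates the composite specificity rule (see [specificity]) for every
#' transcript in every tissue and returns one row per (transcript, tissue)
#' pair with the evidence for each criterion and the final verdict.
#'
#' @param m An [expr_matrix()] with flags populated.
#' @param fc_threshold Minimum fold-change, inclusive (default 5).
#' @param p_threshold Maximum p-value, inclusive (default 0.05).
#' @param fc_method Fold-change denominator rule, see [fold_change()].
#' @param p_adjust `"none"` (default, matching the plain filter) or a
#'   method accepted by [stats::p.adjust()] such as `"BH"`; when set, the
#'   adjusted p-value is used for the criterion and reported in
#'   `p_adjusted`.
#' @return A tibble with columns `transcript_id`, `target_tissue`,
#'   `flag_rule_passed`, `min_fold_change`, `p_value` (plus `p_adjusted`
#'   when requested) and `is_specific`.
#' @export
call_specific <- function(m, fc_threshold = 5, p_threshold = 0.05,
                          fc_method = c("min_pairwise", "pooled"),
                          p_adjust = "none") {
  stopifnot(inherits(m, "expr_matrix"))
  fc_method <- match.arg(fc_method)
  if (is.null(m$flags)) stop("flags not populated; run compute_flags()", call. = FALSE)
  if (fc_threshold < 0 || p_threshold < 0 || p_threshold > 1) {
    stop("invalid thresholds", call. = FALSE)
  }
  pass <- .flag_rule_matrix(m)
  fc <- .fold_change_matrix(m, fc_method)
  pv <- .t_test_matrix(m)
  tiss <- colnames(fc)
  n <- nrow(m$values)
  calls <- tibble::tibble(
    transcript_id = rep(rownames(m$values), times = length(tiss)),
    target_tissue = rep(tiss, each = n),
    flag_rule_passed = as.vector(pass),
    min_fold_change = as.vector(fc),
    p_value = as.vector(pv)
  )
  p_crit <- calls$p_value
  if (!identical(p_adjust, "none")) {
    calls$p_adjusted <- stats::p.adjust(calls$p_value, method = p_adjust)
    p_crit <- calls$p_adjusted
  }
  calls$is_specific <- calls$flag_rule_passed &
    calls$min_fold_change >= fc_threshold &
    p_crit <= p_threshold
  n_per_transcript <- table(calls$transcript_id[calls$is_specific])
  if (any(n_per_transcript > 1)) {
    stop("internal error: transcript called specific in more than one tissue")
  }
  calls
}

#' Count specific transcripts per tissue
#'
#' Summary table in the shape of a per-tissue census: number of specific
#' transcripts in each tissue, split by biotype when a transcript-to-biotype
#' mapping is available.
#'
#' @param calls Output of [call_specific()].
#' @param biotypes Optional named character vector mapping transcript ids
#'   to `"lncRNA"`/`"mRNA"`.
#' @return A tibble with columns `tissue`, (`biotype`,) `n_specific`.
#' @export
specific_counts <- function(calls, biotypes = NULL) {
  sp <- calls[calls$is_specific, , drop = FALSE]
  tiss <- unique(calls$target_tissue)
  if (is.null(biotypes)) {
    n <- vapply(tiss, function(t) sum(sp$target_tissue == t), integer(1))
    return(tibble::tibble(tissue = tiss, n_specific = unname(n)))
  }
  bt <- unname(biotypes[sp$transcript_id])
  if (anyNA(bt)) {
    stop("biotype mapping missing for: ",
         paste(unique(sp$transcript_id[is.na(bt)]), collapse = ", "),
         call. = FALSE)
  }
  grid <- expand.grid(tissue = tiss, biotype = c("lncRNA", "mRNA"),
                      stringsAsFactors = FALSE)
  grid$n_specific <- mapply(
    function(t, b) sum(sp$target_tissue == t & bt == b),
    grid$tissue, grid$biotype)
  tibble::as_tibble(grid)
}

#' Count expressed transcripts per tissue
#'
#' A transcript counts as expressed in a tissue when it is flagged P or M
#' in every replicate of that tissue (detection replicated across the
#' independent sample sets).
#'
#' @param m An [expr_matrix()] with flags populated.
#' @param biotypes Optional named biotype mapping as in [specific_counts()].
#' @return A tibble with columns `tissue`, (`biotype`,) `n_expressed`.
#' @export
expressed_counts <- function(m, biotypes = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(m$flags)) stop("flags not populated; run compute_flags()", call. = FALSE)
  cols <- .tissue_cols(m)
  pm <- m$flags == "P" | m$flags == "M"
  expressed <- vapply(cols, function(cc)
    rowSums(pm[, cc, drop = FALSE]) == length(cc), logical(nrow(m$values)))
  expressed <- matrix(expressed, nrow = nrow(m$values),
                      dimnames = list(rownames(m$values), names(cols)))
  if (is.null(biotypes)) {
    return(tibble::tibble(tissue = colnames(expressed),
                          n_expressed = as.integer(colSums(expressed))))
  }
  bt <- unname(biotypes[rownames(expressed)])
  grid <- expand.grid(tissue = colnames(expressed),
                      biotype = c("lncRNA", "mRNA"), stringsAsFactors = FALSE)
  grid$n_expressed <- mapply(
    function(t, b) sum(expressed[which(bt == b), t]),
    grid$tissue, grid$biotype)
  tibble::as_tibble(grid)
}

#' Transcripts expressed in one tissue
#'
#' @inheritParams expressed_counts
#' @param tissue Tissue label.
#' @return Character vector of transcript ids flagged P or M in every
#'   replicate of `tissue`.
#' @export
expressed_in <- function(m, tissue) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(m$flags)) stop("flags not populated; run compute_flags()", call. = FALSE)
  .tissue_check(m, tissue)
  cc <- which(m$samples$tissue == tissue)
  pm <- m$flags[, cc, drop = FALSE] %in% c("P", "M")
  pm <- matrix(pm, ncol = length(cc))
  rownames(m$values)[rowSums(pm) == length(cc)]
}
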