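#' Background intensity model for detection calls
#'
#' Parameters of the log2-scale background distribution used to assign
#' present/marginal/absent (P/M/A) detection flags. A cell is called present
#' when its log2 intensity is at least `mu + k_present * sigma`, marginal
#' when it is at least `mu + k_marginal * sigma` but below the present
#' threshold, and absent otherwise.
#'
#' @param mu Background mean, log2 intensity units.
#' @param sigma Background standard deviation, log2 units (>= 0).
#' @param k_present Present threshold in background SDs (default 3).
#' @param k_marginal Marginal threshold in background SDs (default 2);
#'   must satisfy `k_present > k_marginal >= 0`.
#' @return An object of class `background_model`.
#' @examples
#' bg <- background_model(6, 1)
#' @export
background_model <- function(mu, sigma, k_present = 3, k_marginal = 2) {
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (!(k_present > k_marginal)) stop("k_present must exceed k_marginal", call. = FALSE)
  if (k_marginal < 0) stop("k_marginal must be >= 0", call. = FALSE)
  structure(
    list(mu = as.numeric(mu), sigma = as.numeric(sigma),
         k_present = as.numeric(k_present), k_marginal = as.numeric(k_marginal)),
    class = "background_model"
  )
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "background model: mu = %.3f, sigma = %.3f (log2); P at mu+%g*sigma, M at mu+%g*sigma\n",
    x$mu, x$sigma, x$k_present, x$k_marginal))
  invisible(x)
}

.FLAG_LEVELS <- c("A", "M", "P")

#' Construct an expression matrix object
#'
#' Container for a transcripts x samples table of normalized linear-scale
#' intensities plus sample metadata (tissue, replicate, source kind) and,
#' optionally, per-cell P/M/A detection flags of identical shape. All
#' intensities must be strictly positive so log2 is defined everywhere.
#'
#' @param values Numeric matrix, rownames = transcript ids, colnames =
#'   sample ids, all values > 0 and finite.
#' @param samples Data frame with columns `sample_id`, `tissue`,
#'   `replicate` and optionally `source_kind` (`"tissue"` or `"cell_line"`,
#'   default `"tissue"`); one row per column of `values`.
#' @param flags Optional character matrix of `"P"`/`"M"`/`"A"` with the
#'   same dimnames as `values`.
#' @return An object of class `expr_matrix` with elements `values`,
#'   `samples`, `flags`.
#' @export
expr_matrix <- function(values, samples, flags = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have transcript rownames and sample colnames", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("missing or non-finite intensities are not allowed", call. = FALSE)
  }
  if (any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1, ]
    stop("non-positive intensity at transcript '", rownames(values)[bad[1]],
         "', sample '", colnames(values)[bad[2]], "'", call. = FALSE)
  }
  samples <- tibble::as_tibble(samples)
  req <- c("sample_id", "tissue", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0) {
    stop("sample metadata missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"source_kind" %in% names(samples)) samples$source_kind <- "tissue"
  if (!all(samples$source_kind %in% c("tissue", "cell_line"))) {
    stop("source_kind must be 'tissue' or 'cell_line'", call. = FALSE)
  }
  unknown <- setdiff(colnames(values), samples$sample_id)
  if (length(unknown) > 0) {
    stop("samples missing from metadata: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  key <- paste(samples$tissue, samples$replicate)
  if (anyDuplicated(key) > 0) {
    stop("duplicate (tissue, replicate) pairs in metadata", call. = FALSE)
  }
  if (!is.null(flags)) flags <- .check_flags(flags, values)
  structure(list(values = values, samples = samples, flags = flags),
            class = "expr_matrix")
}

.check_flags <- function(flags, values) {
  if (!is.matrix(flags)) stop("flags must be a matrix", call. = FALSE)
  flags <- matrix(as.character(flags), nrow = nrow(flags),
                  dimnames = dimnames(flags))
  if (!identical(dim(flags), dim(values))) {
    stop("flags must have the same shape as values", call. = FALSE)
  }
  if (!identical(rownames(flags), rownames(values)) ||
      !identical(colnames(flags), colnames(values))) {
    stop("flags dimnames must match values", call. = FALSE)
  }
  if (!all(flags %in% .FLAG_LEVELS)) {
    stop("flags must be one of 'P', 'M', 'A'", call. = FALSE)
  }
  flags
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d transcripts x %d samples (%d tissue groups)%s\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$tissue)),
              if (is.null(x$flags)) ", no flags" else ", flags set"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Tissues of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character vector of distinct tissue labels, in column order.
#' @export
tissues <- function(m) unique(m$samples$tissue)

#' Read an expression matrix from TSV files
#'
#' The matrix TSV has transcript ids in the first column and sample ids in
#' the header; the metadata TSV maps `sample_id` to `tissue`, `replicate`
#' and optionally `source_kind`; an optional flags TSV of identical shape
#' holds `"P"`/`"M"`/`"A"` calls. Arrays are assumed complete: missing
#' values and non-positive intensities are errors.
#'
#' @param path Matrix TSV.
#' @param metadata_path Sample metadata TSV.
#' @param flags_path Optional flags TSV.
#' @return An [expr_matrix()].
#' @export
read_matrix <- function(path, metadata_path, flags_path = NULL) {
  for (p in c(path, metadata_path, flags_path)) {
    if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
  }
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, row.names = 1,
                           comment.char = "#")
  values <- as.matrix(tab)
  storage.mode(values) <- "double"
  meta <- utils::read.delim(metadata_path, sep = "\t", header = TRUE,
                            check.names = FALSE, comment.char = "#",
                            colClasses = "character")
  if ("replicate" %in% names(meta)) meta$replicate <- as.integer(meta$replicate)
  flags <- NULL
  if (!is.null(flags_path)) {
    ftab <- utils::read.delim(flags_path, sep = "\t", header = TRUE,
                              check.names = FALSE, row.names = 1,
                              comment.char = "#", colClasses = "character")
    flags <- as.matrix(ftab)
  }
  expr_matrix(values, meta, flags)
}

#' Assign present/marginal/absent detection flags
#'
#' Applies the background thresholding rule per cell on log2 intensity `x`:
#' `x >= mu + k_present * sigma` is present (P),
#' `mu + k_marginal * sigma <= x < mu + k_present * sigma` is marginal (M),
#' anything below is absent (A). The assignment is deterministic,
#' idempotent and monotone in intensity. Precomputed flags (for example
#' vendor calls supplied at read time) are kept unless `overwrite = TRUE`.
#'
#' @param m An [expr_matrix()].
#' @param bg A [background_model()].
#' @param overwrite Replace existing flags (default `FALSE`: an error if
#'   flags are already present).
#' @return `m` with the `flags` element populated.
#' @export
compute_flags <- function(m, bg, overwrite = FALSE) {
  stopifnot(inherits(m, "expr_matrix"), inherits(bg, "background_model"))
  if (!is.null(m$flags) && !overwrite) {
    stop("flags already present; use overwrite = TRUE to recompute",
         call. = FALSE)
  }
  x <- log2(m$values)
  thr_p <- bg$mu + bg$k_present * bg$sigma
  thr_m <- bg$mu + bg$k_marginal * bg$sigma
  flags <- matrix("A", nrow = nrow(x), ncol = ncol(x), dimnames = dimnames(x))
  flags[x >= thr_m] <- "M"
  flags[x >= thr_p] <- "P"
  m$flags <- flags
  m
}

#' Median-scale samples of an expression matrix
#'
#' Optional per-sample normalization utility: rescales each column so its
#' median equals a common target (default: the median of the per-sample
#' medians). Off by default throughout the pipeline, which otherwise
#' assumes intensities are already normalized. Flags, if present, are
#' dropped because they no longer describe the scaled values.
#'
#' @param m An [expr_matrix()].
#' @param target Target median on the linear scale; default derived from
#'   the data.
#' @return A rescaled [expr_matrix()] without flags.
#' @export
median_scale <- function(m, target = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  med <- apply(m$values, 2, stats::median)
  if (is.null(target)) target <- stats::median(med)
  scaled <- sweep(m$values, 2, target / med, `*`)
  expr_matrix(scaled, m$samples, flags = NULL)
}
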