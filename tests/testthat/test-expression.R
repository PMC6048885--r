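test_that("matrix TSVs load with validated metadata", {
  d <- tempfile()
  dir.create(d)
  m0 <- make_matrix(list(a = rep(6, 5), b = rep(8, 5), c = rep(10, 5),
                         d = rep(7, 5)))
  write.table(data.frame(transcript_id = rownames(m0$values), m0$values,
                         check.names = FALSE),
              file.path(d, "matrix.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(m0$samples, file.path(d, "meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  m <- read_matrix(file.path(d, "matrix.tsv"), file.path(d, "meta.tsv"))
  expect_equal(dim(m), c(4L, 15L))
  expect_equal(nrow(m$samples), 15)
  expect_equal(sort(tissues(m)), sort(DEFAULT_TISSUES))

  # metadata missing one sample names the offender
  meta_short <- m0$samples[-7, ]
  write.table(meta_short, file.path(d, "meta_short.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_matrix(file.path(d, "matrix.tsv"),
                           file.path(d, "meta_short.tsv")),
               m0$samples$sample_id[7])

  # a zero intensity violates positivity and is located in the message
  vals <- m0$values
  vals[2, 3] <- 0
  write.table(data.frame(transcript_id = rownames(vals), vals,
                         check.names = FALSE),
              file.path(d, "matrix0.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_matrix(file.path(d, "matrix0.tsv"),
                           file.path(d, "meta.tsv")),
               "non-positive")
})

test_that("flag thresholds implement the background k-band rule", {
  bg <- background_model(6, 1)  # P at log2 >= 9, M at >= 8
  m <- make_matrix(list(at_mu = rep(6, 5), marginal = rep(8.5, 5),
                        at_m_edge = rep(8, 5), at_p_edge = rep(9, 5),
                        high = rep(12, 5)))
  f <- compute_flags(m, bg)$flags
  expect_true(all(f["at_mu", ] == "A"))
  expect_true(all(f["marginal", ] == "M"))
  expect_true(all(f["at_m_edge", ] == "M"))  # thresholds are inclusive
  expect_true(all(f["at_p_edge", ] == "P"))
  expect_true(all(f["high", ] == "P"))
})

test_that("planted high expressors all flag present, per-cell recheck", {
  bg <- background_model(6, 1)
  withr::with_seed(11, {
    lv <- matrix(6 + rnorm(50 * 15, 0, 0.25), nrow = 50)
    lv[1:10, ] <- 6 + 6 * 1 + rnorm(10 * 15, 0, 0.25)  # >= mu + 6 sigma
  })
  rows <- setNames(lapply(seq_len(50), function(i) lv[i, ]),
                   sprintf("t%02d", 1:50))
  m <- compute_flags(make_matrix(rows), bg)
  expect_true(all(m$flags[1:10, ] == "P"))
  # brute-force re-application of the rule, cell by cell
  for (i in seq_len(nrow(m$values))) {
    for (j in seq_len(ncol(m$values))) {
      x <- log2(m$values[i, j])
      want <- if (x >= 6 + 3) "P" else if (x >= 6 + 2) "M" else "A"
      expect_identical(m$flags[i, j], want)
    }
  }
})

test_that("flags partition cells and are monotone in intensity", {
  bg <- background_model(6, 1)
  m <- compute_flags(generate_expression(5, n_transcripts = 100)$matrix, bg)
  expect_true(all(m$flags %in% c("P", "M", "A")))
  expect_false(anyNA(m$flags))
  # raising any cell never demotes its flag (A < M < P)
  rank_of <- c(A = 1, M = 2, P = 3)
  m2 <- m
  m2$flags <- NULL
  m2$values <- m$values * 4  # +2 on log2 scale
  m2 <- compute_flags(m2, bg)
  expect_true(all(rank_of[m2$flags] >= rank_of[m$flags]))
})

test_that("flag computation is deterministic, idempotent, and guarded", {
  bg <- background_model(6, 1)
  m <- make_matrix(list(a = c(6, 7, 8, 9, 10)))
  f1 <- compute_flags(m, bg)
  expect_error(compute_flags(f1, bg), "overwrite")
  f2 <- compute_flags(f1, bg, overwrite = TRUE)
  expect_identical(f1$flags, f2$flags)
})

test_that("background model validates its parameters", {
  expect_error(background_model(6, -1), "sigma")
  expect_error(background_model(6, 1, k_present = 2, k_marginal = 2), "exceed")
  expect_error(background_model(6, 1, k_present = 1, k_marginal = -1))
})

test_that("median scaling equalizes per-sample medians and drops flags", {
  withr::with_seed(3, {
    vals <- matrix(2^(6 + rnorm(300)), nrow = 20)
  })
  rownames(vals) <- sprintf("t%02d", 1:20)
  colnames(vals) <- paste0(rep(DEFAULT_TISSUES, each = 3), "_r", 1:3)
  vals[, 1] <- vals[, 1] * 10
  samples <- tibble::tibble(sample_id = colnames(vals),
                            tissue = rep(DEFAULT_TISSUES, each = 3),
                            replicate = rep(1:3, 5))
  m <- compute_flags(expr_matrix(vals, samples), background_model(6, 1))
  s <- median_scale(m)
  med <- apply(s$values, 2, median)
  expect_equal(max(med) / min(med), 1, tolerance = 1e-12)
  expect_null(s$flags)
})
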