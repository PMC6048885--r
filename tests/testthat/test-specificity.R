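test_that("flag rule demands P/M in every target replicate and A elsewhere", {
  m <- make_matrix(list(a = rep(8, 5), b = rep(8, 5), c = rep(8, 5)))
  m <- set_flags(m, list(a = rep("A", 5), b = rep("A", 5), c = rep("A", 5)))
  # craft per-sample flags for the three canonical cases
  fl <- m$flags
  tis <- m$samples$tissue
  fl["a", tis == "testis"] <- c("P", "P", "M")
  fl["a", tis != "testis"] <- "A"
  fl["b", tis == "testis"] <- c("P", "P", "A")
  fl["b", tis != "testis"] <- "A"
  fl["c", tis == "testis"] <- "P"
  fl["c", tis != "testis"] <- "A"
  fl["c", tis == "brain"] <- c("A", "A", "M")
  m$flags <- fl
  expect_true(flag_rule(m, "a", "testis"))
  expect_false(flag_rule(m, "b", "testis"))  # one target replicate absent
  expect_false(flag_rule(m, "c", "testis"))  # non-A outside the target
  expect_error(flag_rule(m, "nope", "testis"), "unknown transcript")
  expect_error(flag_rule(m, "a", "spleen"), "unknown tissue")
})

test_that("fold-change uses the strictest other-tissue denominator", {
  lv <- list(
    x = log2(c(100, 100, 100, 100, 1000)),    # others 100, testis 1000
    y = log2(c(100, 250, 100, 100, 1000)),    # min ratio is vs 250
    z = log2(rep(100, 5))
  )
  m <- make_matrix(lv)
  expect_equal(fold_change(m, "x", "testis"), 10)
  expect_equal(fold_change(m, "y", "testis"), 4)
  expect_equal(fold_change(m, "z", "testis"), 1)
  # pooled variant divides by the pooled other-sample mean
  expect_equal(fold_change(m, "y", "testis", method = "pooled"),
               1000 / mean(rep(c(100, 250, 100, 100), each = 3)))
})

test_that("pooled t-test matches the closed form and stats::t.test", {
  x <- c(10.0, 10.1, 9.9)
  y <- c(3.0, 3.1, 2.9, 3.0, 3.2, 2.8, 3.1, 2.9, 3.0, 3.1, 2.9, 3.0)
  m <- make_matrix(list(t1 = c(y, x)))  # testis gets the last 3 samples
  p <- tissue_t_test(m, "t1", "testis")
  expect_lt(p, 1e-6)
  expect_equal(p, t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)
  # hand-computed pooled-variance t statistic
  sp2 <- (2 * var(x) + 11 * var(y)) / 13
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 12))
  expect_equal(p, 2 * pt(-abs(tstat), 13), tolerance = 1e-12)
})

test_that("t-test conventions: identical groups give p = 1, label swap is neutral", {
  m <- make_matrix(list(flat = rep(8, 5)))
  expect_equal(tissue_t_test(m, "flat", "testis"), 1)
  # two-sided p is invariant under swapping which group is 'target'
  m2 <- make_matrix(list(t1 = c(5, 5, 5, 5, 9)), tissues = c("a", "b", "c", "d", "e"))
  p_hi <- tissue_t_test(m2, "t1", "e")
  m3 <- make_matrix(list(t1 = c(9, 9, 9, 9, 5)), tissues = c("a", "b", "c", "d", "e"))
  expect_equal(tissue_t_test(m3, "t1", "e"), p_hi, tolerance = 1e-12)
})

test_that("specificity verdict is the conjunction of the three criteria", {
  base <- list(
    pass = log2(c(100, 100, 100, 100, 1000)),
    fc_low = log2(c(100, 100, 100, 100, 490)),   # fold 4.9 < 5
    two_tis = log2(c(1000, 100, 100, 100, 1000))
  )
  m <- make_matrix(base)
  # add tiny replicate variation so the t-test has within-group variance
  withr::with_seed(2, {
    m$values <- m$values * 2^matrix(rnorm(length(m$values), 0, 0.01),
                                    nrow = nrow(m$values))
  })
  m <- set_flags(m, list(
    pass = c("A", "A", "A", "A", "P"),
    fc_low = c("A", "A", "A", "A", "P"),
    two_tis = c("P", "A", "A", "A", "P")
  ))
  calls <- call_specific(m)
  get <- function(id, t) calls[calls$transcript_id == id &
                                 calls$target_tissue == t, ]
  expect_true(get("pass", "testis")$is_specific)
  r <- get("fc_low", "testis")
  expect_true(r$flag_rule_passed)
  expect_lt(r$p_value, 0.05)
  expect_false(r$is_specific)  # fold-change 4.9 fails the >= 5 threshold
  expect_false(any(calls$is_specific[calls$transcript_id == "two_tis"]))
})

test_that("calls agree with the naive per-transcript oracle", {
  for (seed in c(21, 22, 23)) {
    ge <- generate_expression(seed, n_transcripts = 80,
                              planted = c(testis = 0.1, brain = 0.05),
                              noise_sd = 0.5)
    m <- compute_flags(ge$matrix, background_model(6, 1))
    calls <- call_specific(m)
    ref <- oracle_specific(m)
    got <- calls[order(calls$transcript_id, calls$target_tissue), ]
    ref <- ref[order(ref$transcript_id, ref$target_tissue), ]
    expect_equal(got$is_specific, ref$is_specific)
  }
})

test_that("tightening thresholds never yields more calls", {
  ge <- generate_expression(31, n_transcripts = 300, noise_sd = 0.6,
                            planted = c(testis = 0.1), fold = 8)
  m <- compute_flags(ge$matrix, background_model(6, 1))
  n_calls <- function(fc, p) sum(call_specific(m, fc, p)$is_specific)
  base <- n_calls(5, 0.05)
  expect_lte(n_calls(8, 0.05), base)
  expect_lte(n_calls(5, 0.01), base)
  expect_lte(n_calls(8, 0.01), base)
})

test_that("no transcript is specific to two tissues, even under noise", {
  for (seed in c(41, 42)) {
    ge <- generate_expression(seed, n_transcripts = 400, noise_sd = 0.8,
                              planted = c(testis = 0.05, liver = 0.05))
    m <- compute_flags(ge$matrix, background_model(6, 1))
    calls <- call_specific(m)
    per_transcript <- table(calls$transcript_id[calls$is_specific])
    expect_true(all(per_transcript <= 1))
  }
})

test_that("per-tissue summary counts split by biotype", {
  ge <- generate_expression(51, n_transcripts = 100,
                            planted = c(testis = 0.1), noise_sd = 0)
  m <- compute_flags(ge$matrix, background_model(6, 1))
  calls <- call_specific(m)
  bt <- setNames(rep(c("lncRNA", "mRNA"), 50), rownames(m$values))
  counts <- specific_counts(calls, bt)
  expect_equal(sum(counts$n_specific), sum(calls$is_specific))
  plain <- specific_counts(calls)
  expect_equal(plain$n_specific[plain$tissue == "testis"],
               length(ge$truth$specific_transcripts$testis))
  ec <- expressed_counts(m)
  expect_true(all(ec$n_expressed >= plain$n_specific))
})
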