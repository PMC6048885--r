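test_that("percentages round half-up, not banker's", {
  expect_equal(proportion(1, 8, 0), 13)     # 12.5 rounds up
  expect_equal(proportion(1, 8, 1), 12.5)
  expect_equal(proportion(25, 1000, 1), 2.5)
  expect_equal(proportion(0, 50, 0), 0)
  expect_equal(proportion(c(1, 3), c(4, 4), 0), c(25, 75))
  expect_error(proportion(1, 0, 0), "denominator")
  expect_error(proportion(5, 4, 0), "exceed")
  expect_error(proportion(-1, 4, 0))
})

test_that("chromosome ratios divide specific by expressed totals per biotype", {
  ann <- rbind(
    do.call(rbind, lapply(1:100, function(i) {
      make_lnc(sprintf("l%03d", i), "chrA", i * 1000, i * 1000 + 500)
    })),
    do.call(rbind, lapply(1:40, function(i) {
      make_gene(sprintf("m%03d", i), "chrA", i * 2000, i * 2000 + 900)
    })),
    make_gene("m_only", "chrB", 1000, 2000)
  )
  spec <- c(sprintf("l%03d", 1:21), sprintf("m%03d", 1:4))
  calls <- tibble::tibble(
    transcript_id = ann$transcript_id,
    target_tissue = "testis",
    is_specific = ann$transcript_id %in% spec
  )
  cd <- chrom_distribution(calls, ann)
  a <- cd[cd$chrom == "chrA", ]
  expect_equal(a$ratio_lnc, 0.21)
  expect_equal(a$ratio_mrna, 4 / 40)
  b <- cd[cd$chrom == "chrB", ]
  expect_true(b$degenerate_lnc)
  expect_equal(b$ratio_lnc, 0)
  expect_equal(sum(cd$n_specific_lnc) + sum(cd$n_specific_mrna), length(spec))
  # a specific transcript with no annotation is an error naming the id
  calls2 <- rbind(calls, tibble::tibble(transcript_id = "ghost",
                                        target_tissue = "testis",
                                        is_specific = TRUE))
  expect_error(chrom_distribution(calls2, ann), "ghost")
})

test_that("uniformly planted specific transcripts give near-equal ratios", {
  withr::with_seed(17, {
    chroms <- paste0("chr", 1:5)
    ann <- do.call(rbind, lapply(seq_along(chroms), function(c) {
      do.call(rbind, lapply(1:200, function(i) {
        make_lnc(sprintf("%s_l%03d", chroms[c], i), chroms[c],
                 i * 1000, i * 1000 + 400)
      }))
    }))
    spec <- ann$transcript_id[runif(nrow(ann)) < 0.2]
  })
  calls <- tibble::tibble(transcript_id = ann$transcript_id,
                          target_tissue = "testis",
                          is_specific = ann$transcript_id %in% spec)
  cd <- chrom_distribution(calls, ann)
  # each per-chromosome ratio within a 4-sigma binomial band of the rate
  band <- 4 * sqrt(0.2 * 0.8 / 200)
  expect_true(all(abs(cd$ratio_lnc - 0.2) < band))
})

test_that("venn regions partition the union", {
  # three cell-line sets built from fixed exclusive region sizes
  region_sizes <- c(F9 = 34, `GC-1` = 48, `GC-2` = 32,
                    `F9&GC-1` = 20, `F9&GC-2` = 19, `GC-1&GC-2` = 20,
                    `F9&GC-1&GC-2` = 55)
  ids <- sprintf("lnc%04d", seq_len(sum(region_sizes)))
  assign_region <- rep(names(region_sizes), region_sizes)
  sets <- lapply(c("F9", "GC-1", "GC-2"), function(s) {
    ids[vapply(strsplit(assign_region, "&"), function(r) s %in% r, logical(1))]
  })
  names(sets) <- c("F9", "GC-1", "GC-2")
  expect_equal(lengths(sets), c(F9 = 128, `GC-1` = 143, `GC-2` = 126))
  ov <- set_overlap(sets)
  expect_equal(ov$union_size, 228)
  expect_equal(ov$intersection_size, 55)
  expect_equal(sum(ov$regions$n), ov$union_size)
  got <- setNames(ov$regions$n, ov$regions$region)
  expect_equal(got[names(region_sizes)], region_sizes)
})

test_that("venn handles disjoint sets and duplicate ids", {
  ov <- set_overlap(list(a = c("x", "y"), b = c("z")))
  expect_equal(ov$union_size, 3)
  expect_equal(ov$intersection_size, 0)
  expect_equal(ov$regions$n[ov$regions$region == "a&b"], 0)
  expect_warning(ov2 <- set_overlap(list(a = c("x", "x"), b = "x")),
                 "duplicate")
  expect_equal(ov2$union_size, 1)
  expect_error(set_overlap(list(a = "x")), ">= 2")
})

test_that("first-detection day maps to the spermatogenic stage timeline", {
  days <- default_stage_days()
  det_at <- function(day) days >= day
  expect_equal(stage_assignment(det_at(7))$inferred_stage, "mitotic_or_earlier")
  expect_equal(stage_assignment(det_at(14))$inferred_stage, "early_spermatocyte")
  expect_equal(stage_assignment(det_at(16))$inferred_stage, "pachytene_spermatocyte")
  s21 <- stage_assignment(det_at(21))
  expect_equal(s21$inferred_stage, "round_spermatid")
  expect_equal(s21$first_detection_day, 21L)
  none <- stage_assignment(rep(FALSE, length(days)))
  expect_equal(none$inferred_stage, "undetected")
  expect_true(is.na(none$first_detection_day))
  expect_error(stage_assignment(logical(0), days = integer(0)), "empty")
})

test_that("later first detection never maps to an earlier stage", {
  order_of <- c(mitotic_or_earlier = 1, early_spermatocyte = 2,
                pachytene_spermatocyte = 3, round_spermatid = 4)
  days <- default_stage_days()
  stages <- vapply(days, function(d) {
    stage_assignment(days >= d)$inferred_stage
  }, character(1))
  expect_true(all(diff(order_of[stages]) >= 0))
})

test_that("germ-cell specificity is presence in wild type and absence in mutant", {
  tab <- germ_cell_call(c(TRUE, TRUE, FALSE, FALSE),
                        c(FALSE, TRUE, FALSE, TRUE),
                        transcript_id = sprintf("t%d", 1:4))
  expect_equal(tab$germ_cell_specific, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(germ_cell_call(NA, TRUE), "TRUE/FALSE")
})

test_that("relative quantification follows 2^-ddCt", {
  expect_equal(ddct_quantify(20, 18, 25, 18), 32)
  expect_equal(ddct_quantify(18, 15, 20, 15), 4)  # two cycles earlier
  withr::with_seed(9, {
    a <- runif(20, 5, 40)
    b <- runif(20, 5, 40)
  })
  expect_equal(ddct_quantify(a, b, a, b), rep(1, 20))
  expect_error(ddct_quantify(Inf, 18, 25, 18), "finite")
})
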