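test_that("quantile normalization equalizes column distributions", {
  # forced arithmetic: columns (1,3) and (2,6) both become (1.5, 4.5)
  m <- expression_matrix(matrix(c(1, 3, 2, 6), 2, 2,
                                dimnames = list(c("g1", "g2"), c("s1", "s2"))))
  q <- quantile_normalize(m)
  expect_equal(unname(q[, 1]), c(1.5, 4.5))
  expect_equal(unname(q[, 2]), c(1.5, 4.5))

  # columns already sharing a distribution are a fixed point
  set.seed(1)
  v <- sort(rnorm(30))
  m2 <- expression_matrix(cbind(s1 = v, s2 = sample(v), s3 = sample(v)),
                          gene_ids = paste0("g", 1:30))
  expect_equal(quantile_normalize(m2), m2, tolerance = 1e-12)

  # post-condition on random input: all column-sorted vectors identical,
  # equal to the cross-column mean of order statistics; rank order kept
  set.seed(2)
  m3 <- expression_matrix(matrix(rnorm(250), 50, 5,
                                 dimnames = list(paste0("g", 1:50), paste0("s", 1:5))))
  q3 <- quantile_normalize(m3)
  ref <- rowMeans(apply(m3, 2, sort))
  for (j in 1:5) {
    expect_equal(unname(sort(q3[, j])), ref, tolerance = 1e-12)
    expect_equal(rank(q3[, j]), rank(m3[, j]))
  }

  # idempotent
  expect_equal(quantile_normalize(q3), q3, tolerance = 1e-12)

  single <- m3[, 1, drop = FALSE]
  attr(single, "scale_tag") <- "absolute_log2"
  expect_warning(out <- quantile_normalize(single), "single|>=2|unchanged")
  expect_equal(out, single)
})

test_that("rank-invariant normalization maps sample onto the baseline", {
  set.seed(5)
  base <- sort(rnorm(1000, 7, 1))
  names(base) <- paste0("g", seq_along(base))
  base <- sample(base)

  # identity when sample equals baseline
  expect_equal(rank_invariant_normalize(base, base), base, tolerance = 1e-9)

  # constant shift is removed almost exactly
  shifted <- base + 0.7
  out <- rank_invariant_normalize(shifted, base)
  expect_lt(max(abs(out - base)), 0.05)

  # monotone cubic distortion: output closer to baseline than input
  distorted <- base + 0.02 * (base - 7)^3 + 0.3
  out2 <- rank_invariant_normalize(distorted, base)
  expect_gt(cor(out2, base), cor(distorted, base))
  expect_lt(mean(abs(out2 - base)), mean(abs(distorted - base)))
})

test_that("rank-invariant normalization falls back when the invariant set is tiny", {
  set.seed(6)
  base <- setNames(rnorm(200, 7, 1), paste0("g", 1:200))
  scrambled <- setNames(sample(base), names(base))   # ranks destroyed
  expect_warning(out <- rank_invariant_normalize(scrambled, base), "median-shift")
  expect_equal(median(out), median(base))
})

test_that("median polish summarization matches its definition and an oracle", {
  samples <- paste0("s", 1:4)
  map <- data.frame(probe_id = c(paste0("gA_p", 1:3), "gB_p1"),
                    gene_id = c("gA", "gA", "gA", "gB"), stringsAsFactors = FALSE)

  # constant matrix: every summary equals the constant
  const <- matrix(3.25, 4, 4, dimnames = list(map$probe_id, samples))
  s1 <- median_polish_summarize(const, map)
  expect_true(all(s1 == 3.25))

  # single-probe gene: summary equals the probe row
  set.seed(8)
  x <- matrix(rnorm(16), 4, 4, dimnames = list(map$probe_id, samples))
  s2 <- median_polish_summarize(x, map)
  expect_equal(unname(s2["gB", ]), unname(x["gB_p1", ]))

  # random blocks agree with the independent iterative-median oracle
  map8 <- data.frame(probe_id = paste0("gC_p", 1:8), gene_id = "gC",
                     stringsAsFactors = FALSE)
  for (k in 1:5) {
    block <- matrix(rnorm(32, 7, 1), 8, 4,
                    dimnames = list(map8$probe_id, samples))
    got <- median_polish_summarize(block, map8)
    mp <- oracle_median_polish(block)
    expect_equal(unname(got["gC", ]), unname(mp$overall + mp$col),
                 tolerance = 1e-6)
  }
})

test_that("median polish summaries ignore probe-row order", {
  set.seed(9)
  map <- data.frame(probe_id = paste0("p", 1:6), gene_id = "gA",
                    stringsAsFactors = FALSE)
  block <- matrix(rnorm(24, 6, 1), 6, 4,
                  dimnames = list(map$probe_id, paste0("s", 1:4)))
  perm <- sample(6)
  s_orig <- median_polish_summarize(block, map)
  s_perm <- median_polish_summarize(block[perm, ], map)
  expect_equal(s_orig, s_perm, tolerance = 1e-9)
})

test_that("fold-change assembly subtracts the matched vehicle median", {
  genes <- paste0("g", 1:40)
  set.seed(10)
  veh <- matrix(rnorm(120, 7, 1), 40, 3,
                dimnames = list(genes, c("v1", "v2", "v3")))
  treated <- matrix(rnorm(80, 7, 1), 40, 2,
                    dimnames = list(genes, c("t1", "t2")))
  md <- data.frame(sample_id = c("t1", "t2", "v1", "v2", "v3"),
                   drug_name = c("dA", "dB", "", "", ""),
                   cell_line = "MCF7", dose = "", batch = "b1",
                   role = c("treated", "treated", rep("vehicle", 3)),
                   stringsAsFactors = FALSE)
  fc <- assemble_fold_change(expression_matrix(treated),
                             expression_matrix(veh), md)
  expect_identical(scale_tag(fc), "log2_fold_change")
  # oracle recomputation gene by gene
  for (g in sample(genes, 5)) {
    expect_equal(fc[g, "t1"], treated[g, "t1"] - median(veh[g, ]))
  }

  # treated equal to the vehicle median gives an all-zero column
  treated0 <- treated
  treated0[, "t1"] <- apply(veh, 1, median)
  fc0 <- assemble_fold_change(expression_matrix(treated0),
                              expression_matrix(veh), md)
  expect_true(all(fc0[, "t1"] == 0))

  # a single vehicle means plain subtraction of that column
  fc1 <- assemble_fold_change(expression_matrix(treated),
                              expression_matrix(veh[, "v1", drop = FALSE]),
                              md[md$sample_id %in% c("t1", "t2", "v1"), ])
  expect_equal(unname(fc1[, "t2"]), unname(treated[, "t2"] - veh[, "v1"]))
})

test_that("treated samples without vehicles are excluded with a warning", {
  genes <- paste0("g", 1:10)
  treated <- matrix(rnorm(20), 10, 2, dimnames = list(genes, c("t1", "t2")))
  veh <- matrix(rnorm(10), 10, 1, dimnames = list(genes, "v1"))
  md <- data.frame(sample_id = c("t1", "t2", "v1"),
                   drug_name = c("dA", "dB", ""),
                   cell_line = "MCF7", dose = "",
                   batch = c("b1", "b2", "b1"),   # t2 has no batch-b2 vehicle
                   role = c("treated", "treated", "vehicle"),
                   stringsAsFactors = FALSE)
  expect_warning(fc <- assemble_fold_change(expression_matrix(treated),
                                            expression_matrix(veh), md),
                 "t2")
  expect_identical(colnames(fc), "t1")
  expect_identical(attr(fc, "excluded"), "t2")
})

test_that("fold changes of vehicle-like treated samples center near zero", {
  set.seed(12)
  genes <- paste0("g", 1:500)
  veh <- matrix(rnorm(500 * 4, 7, 1), 500, 4,
                dimnames = list(genes, paste0("v", 1:4)))
  treated <- matrix(rnorm(500 * 3, 7, 1), 500, 3,
                    dimnames = list(genes, paste0("t", 1:3)))
  md <- data.frame(sample_id = c(paste0("t", 1:3), paste0("v", 1:4)),
                   drug_name = c("dA", "dA", "dA", rep("", 4)),
                   cell_line = "MCF7", dose = "", batch = "b1",
                   role = c(rep("treated", 3), rep("vehicle", 4)),
                   stringsAsFactors = FALSE)
  fc <- assemble_fold_change(expression_matrix(treated),
                             expression_matrix(veh), md)
  se_median <- 1.2533 * apply(fc, 2, sd) / sqrt(nrow(fc))
  expect_true(all(abs(apply(fc, 2, median)) < 3 * se_median))
})
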