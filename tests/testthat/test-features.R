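test_that("primary weights follow class median differences", {
  p <- tiny_panel()
  set.seed(11)
  base <- matrix(stats::rlnorm(40 * 5, 2, 0.3), 40, 5)
  pos <- mat_cohort(base[1:20, ], p)
  sus <- mat_cohort(base[21:40, ], p)
  # identically distributed (same draw pool): shift one analyte by 10x
  shifted <- base[1:20, ]
  shifted[, 1] <- shifted[, 1] * 10
  pos10 <- mat_cohort(shifted, p)
  w <- compute_primary_weights(pos10, sus)
  expect_equal(w$analyte, as.character(p))
  expect_equal(which.max(w$weight), 1L)  # planted shift wins
  # D matches brute-force medians
  expect_equal(w$D[1], median(shifted[, 1]) - median(base[21:40, 1]))
  # sign(weight) == sign(D) everywhere
  expect_true(all(sign(w$weight) == sign(w$D)))
  # negating the shift flips the sign
  shrunk <- base[1:20, ]
  shrunk[, 1] <- shrunk[, 1] / 10
  w2 <- compute_primary_weights(mat_cohort(shrunk, p), sus)
  expect_lt(w2$weight[1], 0)
  expect_gt(w$weight[1], 0)
})

test_that("primary weights are scale-equivariant in D and sign-stable", {
  p <- tiny_panel()
  set.seed(12)
  pos <- rand_cohort(15, seed = 21)
  sus <- rand_cohort(15, seed = 22)
  w <- compute_primary_weights(pos, sus)
  c_mult <- 3.7
  pos2 <- pos; sus2 <- sus
  pos2$values[, 2] <- pos2$values[, 2] * c_mult
  sus2$values[, 2] <- sus2$values[, 2] * c_mult
  w2 <- compute_primary_weights(pos2, sus2)
  expect_equal(w2$D[2], c_mult * w$D[2])
  expect_equal(sign(w2$weight[2]), sign(w$weight[2]))
  expect_equal(w2$D[-2], w$D[-2])
})

test_that("degenerate analytes fall back from IQR to sd to unit scale", {
  p <- analyte_panel(c("A", "B"))
  # analyte A constant in both classes: IQR 0, sd 0 -> unit scale, weight 0
  pos <- mat_cohort(cbind(A = rep(5, 4), B = c(1, 2, 3, 4)), p)
  sus <- mat_cohort(cbind(A = rep(5, 4), B = c(1, 1, 2, 2)), p)
  w <- compute_primary_weights(pos, sus)
  expect_equal(w$scale_type[1], "unit")
  expect_equal(w$weight[1], 0)
  expect_error(compute_primary_weights(pos[integer(0)], sus),
               class = "nbs_insufficient_data")
})

test_that("select_signed_top returns up to k markers per sign", {
  w <- structure(
    data.frame(analyte = LETTERS[1:8],
               D = c(3, 2, 1, -1, -2, -3, 0, 0),
               scale = 1, scale_type = "iqr",
               weight = c(3, 2, 1, -1, -2, -3, 0, 0)),
    class = c("primary_weights", "data.frame"))
  top <- select_signed_top(w, k = 3)
  expect_equal(top$positive, c("A", "B", "C"))
  expect_equal(top$negative, c("F", "E", "D"))
  # only 2 positive weights present -> positive list of length 2
  w2 <- w; w2$weight[3] <- 0
  expect_length(select_signed_top(w2, 3)$positive, 2L)
  # all-zero weights -> both lists empty
  w3 <- w; w3$weight[] <- 0
  expect_equal(lengths(select_signed_top(w3, 3)), c(positive = 0L, negative = 0L))
})

test_that("manifested feature enumeration counts products and ratios", {
  specs <- build_manifested_features(c("A", "B", "C"), c("X", "Y", "Z"))
  expect_length(specs, choose(6, 2) + 9)  # 24
  # general count law over marker list sizes
  for (p in 0:3) for (n in 0:3) {
    pos <- LETTERS[seq_len(p)]
    neg <- letters[seq_len(n)]
    expect_length(build_manifested_features(pos, neg),
                  choose(p + n, 2) + p * n)
  }
  expect_length(build_manifested_features(character(0), character(0)), 0L)
  expect_error(build_manifested_features(c("A"), c("A", "B")),
               class = "nbs_config_error")
})

test_that("manifested features use the published display dialect", {
  specs <- build_manifested_features(c("C5OH", "Orn", "Arg"),
                                     c("C16", "C4", "C16:1"))
  disp <- vapply(specs, function(s) s$display, character(1))
  expect_true("Orn/C16" %in% disp)          # cross ratio
  specs2 <- build_manifested_features(c("Phe"), c("Leu", "Tyr"))
  disp2 <- vapply(specs2, function(s) s$display, character(1))
  expect_true("Leu×Tyr" %in% disp2)    # within-negative product
  # product operand order is canonical: A x B == B x A
  expect_identical(feature_spec("product", c("Tyr", "Leu"))$display,
                   feature_spec("product", c("Leu", "Tyr"))$display)
  # parse round-trip
  back <- parse_features(disp)
  expect_identical(vapply(back, function(s) s$display, character(1)), disp)
})

test_that("feature evaluation does products, ratios and the epsilon guard", {
  rec <- c(Leu = 2, Tyr = 3, Orn = 5, C16 = 2)
  expect_equal(unclass(evaluate_feature(rec, feature_spec("product", c("Leu", "Tyr")))),
               6, ignore_attr = TRUE)
  expect_equal(unclass(evaluate_feature(rec, feature_spec("ratio", c("Orn", "C16")))),
               2.5, ignore_attr = TRUE)
  rec0 <- c(Orn = 5, C16 = 0)
  v <- evaluate_feature(rec0, feature_spec("ratio", c("Orn", "C16")))
  expect_equal(as.numeric(v), 5 / 1e-6)
  expect_true(attr(v, "guarded"))
  expect_error(evaluate_feature(rec, feature_spec("raw", "Phe")),
               class = "nbs_config_error")
})

test_that("f_score matches the hand-worked example and its invariances", {
  expect_equal(f_score(c(4, 6), c(0, 2)), 2.0)
  expect_equal(f_score(c(1, 1, 1), c(1, 1, 1)), 0)
  set.seed(31)
  for (i in 1:20) {
    a <- stats::rnorm(sample(3:10, 1)); b <- stats::rnorm(sample(3:10, 1))
    # symmetry under class swap and invariance to common shifts
    expect_equal(f_score(a, b), f_score(b, a))
    expect_equal(f_score(a + 7.3, b + 7.3), f_score(a, b))
    # brute-force oracle from raw sums
    expect_equal(f_score(a, b), brute_f_score(a, b))
  }
  # zero-variance classes
  expect_equal(f_score(c(2, 2), c(2, 2)), 0)
  expect_identical(f_score(c(2, 2), c(3, 3)), Inf)
  expect_error(f_score(1, c(1, 2)), class = "nbs_insufficient_data")
})

test_that("rank_features puts a planted informative feature first", {
  p <- analyte_panel(c("M1", "N1", "N2", "N3"))
  set.seed(41)
  n <- 40
  vals <- matrix(stats::rlnorm(n * 4, 1, 0.4), n, 4)
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  vals[lab, 1] <- vals[lab, 1] * 50  # huge effect on M1 in positives
  co <- mat_cohort(vals, p)
  cands <- lapply(as.character(p), function(a) feature_spec("raw", a))
  rk <- rank_features(co, lab, cands, top = 10)
  expect_equal(rk$feature[1], "M1")
  expect_true(all(diff(rk$f_score) <= 0))
  # f-scores agree with brute force on the evaluated matrix
  for (j in 1:4) {
    expect_equal(rk$f_score[rk$feature == as.character(p)[j]],
                 brute_f_score(vals[lab, j], vals[!lab, j]))
  }
  expect_equal(nrow(rank_features(co, lab, cands, top = 0)), 0L)
  expect_equal(nrow(rank_features(co, lab, cands, top = 99)), 4L)
})
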