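test_that("univariate scaling maps 0 to 0 and the column max to 10", {
  sc <- scale_univariate(c(2, 4, 8))
  expect_equal(sc$scaled, c(2.5, 5, 10))
  expect_equal(unname(sc$anchors), c(0, 8))
  # the published P1 range: the observed maximum maps to 10
  expect_equal(scale_univariate(c(93.67, 10))$scaled[1], 10)
  expect_equal(scale_univariate(c(0, 5))$scaled[1], 0)
  expect_error(scale_univariate(c(-1, 3)), "negative")
  expect_error(scale_univariate(c(NA, NA)), "non-missing")
  expect_warning(sc0 <- scale_univariate(c(0, 0)), "degenerate")
  expect_equal(sc0$scaled, c(0, 0))
})

test_that("scaling is idempotent with the same anchors, monotone, bounded", {
  set.seed(2)
  v <- runif(12, 0, 50)
  sc <- scale_univariate(v)
  again <- scale_univariate(sc$scaled, anchor_max = 10)
  expect_equal(again$scaled, sc$scaled)
  expect_true(all(sc$scaled >= 0 & sc$scaled <= 10))
  expect_equal(order(sc$scaled), order(v))
})

test_that("delta of a strain against itself is zero and never relevant", {
  means <- matrix(rep(c(40, 20, 3, 2, 1.5), each = 2), 2, byrow = FALSE)
  ex <- make_experiments(c("WT_01", "G1"), c("01", "01"),
                         c("wildtype", "modified"), means, sd = 2, n = 4)
  ex[ex$strain_id == "G1", paste0("P", 1:5)] <-
    ex[ex$strain_id == "WT_01", paste0("P", 1:5)]
  dm <- build_delta_matrix(scale_strain_means(summarize_strains(ex)))
  expect_true(all(abs(dm$delta) < 1e-10))
  expect_false(any(dm$relevant))
})

test_that("a planted scaled effect is recovered and flagged relevant", {
  errs <- flags <- numeric(10)
  for (k in 1:10) {
    eff <- matrix(0, 4, 5); eff[1, 1] <- -4
    tr <- generate_strain_table(n_wildtype_sets = 4, n_modified = 4,
                                planted_effects = eff, group_sd = 0.5,
                                baseline_cv = c(P1 = 0, P2 = 0, P3 = 0,
                                                P4 = 0, P5 = 0), seed = 100 + k)
    sm <- scale_strain_means(summarize_strains(tr$experiments),
                             anchors = tr$anchors)
    dm <- build_delta_matrix(sm)
    errs[k] <- dm$delta["G01", "M1.P1"] + 4
    flags[k] <- dm$relevant["G01", "M1.P1"] &&
      dm$delta["G01", "M1.P1"] < 0
  }
  expect_lt(abs(mean(errs)), 0.5)
  expect_true(all(flags == 1))
})

test_that("null effects are rarely flagged by the composite mean +/- SD rule", {
  tr <- generate_strain_table(n_wildtype_sets = 20, n_modified = 200,
                              planted_effects = 0, group_sd = 1, seed = 77)
  dm <- build_delta_matrix(scale_strain_means(summarize_strains(tr$experiments)))
  expect_lte(mean(dm$relevant), 0.35)
})

test_that("delta_heatmap pairs by database id and supports both composites", {
  m1 <- summarize_strain(make_experiments("G1", "01", "modified",
                                          matrix(30, 1, 5), sd = 0, n = 3))
  w1 <- summarize_strain(make_experiments("W1", "01", "wildtype",
                                          matrix(40, 1, 5), sd = 0, n = 4))
  w2 <- summarize_strain(make_experiments("W2", "02", "wildtype",
                                          matrix(40, 1, 5), sd = 0, n = 4))
  anchors <- stats::setNames(rep(40, 5), paste0("M1.P", 1:5))
  d <- delta_heatmap(m1, w1, anchors)
  expect_equal(d$delta[d$parameter == "P1"], -2.5)  # (30-40)/40*10
  expect_error(delta_heatmap(m1, w2, anchors), "pairing error")

  # composite rules: rms vs max
  s1 <- 2; s2 <- 4
  expect_equal(thrombomap:::combine_sd(s1, s2, "rms"), sqrt((4 + 16) / 2))
  expect_equal(thrombomap:::combine_sd(s1, s2, "max"), 4)
})

test_that("effect sums use filtered deltas and the requested surface", {
  d <- matrix(c(5, -2, -2, -2, -2,
                0, 0.4, -0.3, 0, 0), 2, 5, byrow = TRUE,
              dimnames = list(c("G01", "G02"), paste0("M1.P", 1:5)))
  rel <- matrix(c(TRUE, TRUE, TRUE, TRUE, TRUE,
                  FALSE, FALSE, FALSE, FALSE, FALSE), 2, 5, byrow = TRUE,
                dimnames = dimnames(d))
  dm <- fake_delta_matrix(d, rel)
  sig <- effect_sum(dm, c("P2", "P3", "P4", "P5"), "M1")
  expect_equal(sig[["G01"]], -8)   # P1 excluded from the signature
  expect_equal(sig[["G02"]], 0)    # sub-threshold cells count as unchanged
  expect_equal(effect_sum(dm, "P1", "M1")[["G01"]], 5)
  expect_error(effect_sum(dm, surface = "M9"), "no matching columns")
})
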