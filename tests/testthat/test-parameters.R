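test_that("parameter validation enforces ranges and half-step scores", {
  expect_error(image_parameters(P3 = 5.5), "valid range")
  expect_error(image_parameters(P4 = 3.5), "valid range")
  expect_error(image_parameters(P5 = -1), "valid range")
  expect_error(image_parameters(P1 = 101), "valid range")
  expect_error(image_parameters(P3 = 2.3), "0.5 increments")
  expect_silent(image_parameters(P3 = 2.5, P4 = 1, P5 = 0))
  expect_error(image_parameters(P1 = 10, P2 = 12), "cannot exceed")
})

test_that("experiment averaging is the per-parameter mean", {
  imgs <- lapply(c(10, 20, 30), function(v)
    image_parameters(P1 = v, surface = "M1"))
  avg <- average_experiment(imgs)
  expect_equal(unname(avg$values[["P1"]]), 20)

  one <- image_parameters(P1 = 42, P3 = 2.5)
  expect_equal(average_experiment(list(one))$values, one$values)

  # partial fluorescence panel: averaged over available images, with warning
  imgs2 <- list(image_parameters(P1 = 10, P6 = 4),
                image_parameters(P1 = 20, P6 = 6),
                image_parameters(P1 = 30))
  expect_warning(avg2 <- average_experiment(imgs2), "P6")
  expect_equal(unname(avg2$values[["P6"]]), 5)
  expect_equal(unname(avg2$values[["P1"]]), 20)

  expect_error(average_experiment(list(
    image_parameters(P1 = 1, surface = "M1"),
    image_parameters(P1 = 2, surface = "M2"))), "mixed surfaces")
  expect_error(average_experiment(list()), "no images")
})

test_that("strain summaries use sample SD and the inclusion rule", {
  recs <- make_experiments("Gx", "01", "modified",
                           matrix(34, 1, 5), sd = 0, n = 3)
  recs$P1 <- c(30, 34, 38)
  s <- summarize_strain(recs)
  expect_equal(s$mean[s$parameter == "P1"], 34)
  expect_equal(s$sd[s$parameter == "P1"], 4)
  expect_equal(s$n[s$parameter == "P1"], 3L)

  wt <- make_experiments("WTx", "01", "wildtype", matrix(40, 1, 5), n = 4)
  sw <- summarize_strain(wt)
  expect_equal(sw$mean[sw$parameter == "P1"], 40)
  expect_equal(sw$sd[sw$parameter == "P1"], 0)

  # inclusion: modified needs >= 3, wild-type >= 4
  expect_error(summarize_strain(recs[1:2, ]), "exclusion.*Gx")
  expect_error(summarize_strain(wt[1:3, ]), "exclusion")
  expect_silent(summarize_strain(wt[1:3, ], enforce_inclusion = FALSE))
  expect_error(summarize_strain(recs[0, ]), "zero experiment")
})

test_that("summarizing pre-averaged inputs equals averaging then summarizing", {
  # two experiments, each from three images: averaging per experiment first
  # and summarizing is the same as summarizing the per-experiment means
  imgs_a <- lapply(c(10, 20, 30), function(v) image_parameters(P1 = v))
  imgs_b <- lapply(c(40, 50, 60), function(v) image_parameters(P1 = v))
  means <- c(average_experiment(imgs_a)$values[["P1"]],
             average_experiment(imgs_b)$values[["P1"]])
  recs <- make_experiments("Gy", "01", "modified", matrix(0, 1, 5), n = 2)
  recs$P1 <- means
  s <- summarize_strain(recs, enforce_inclusion = FALSE)
  expect_equal(s$mean[s$parameter == "P1"], mean(c(20, 50)))
})

test_that("thrombus signature is the sum of scaled P2-P5", {
  expect_equal(as.numeric(thrombus_signature(c(P2 = 10, P3 = 10, P4 = 10, P5 = 10))), 40)
  expect_equal(as.numeric(thrombus_signature(c(P2 = 0, P3 = 0, P4 = 0, P5 = 0))), 0)
  sig <- thrombus_signature(c(P2 = 4, P3 = 5, P4 = 6, P5 = 5))
  expect_equal(as.numeric(sig), 20)
  expect_equal(attr(sig, "normalized"), 5)
  expect_true(is.na(thrombus_signature(c(P2 = 4, P3 = 5, P4 = 6))))
  expect_error(thrombus_signature(c(P2 = 11, P3 = 1, P4 = 1, P5 = 1)), "0, 10")
})

test_that("signature is monotone in each component", {
  set.seed(13)
  for (rep in 1:20) {
    v <- round(runif(4, 0, 9), 1)
    names(v) <- c("P2", "P3", "P4", "P5")
    base <- as.numeric(thrombus_signature(v))
    k <- sample(4, 1)
    v2 <- v; v2[k] <- v2[k] + runif(1, 0, 10 - v2[k])
    expect_gte(as.numeric(thrombus_signature(v2)), base)
  }
})

test_that("experiment_record validates shear rate and surface agreement", {
  p <- image_parameters(P1 = 30, surface = "M1")
  expect_error(experiment_record("G", "01", "modified", "M1", p,
                                 shear_rate_per_s = 1500), "1000 or 1700")
  r <- experiment_record("G", "01", "modified", "M1", p,
                         shear_rate_per_s = 1700)
  expect_equal(r$P1, 30)
  expect_error(experiment_record("G", "01", "modified", "M2", p))
})
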