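test_that("tau-b reproduces hand-counted examples", {
  expect_equal(kendall_tau_b(1:4, 1:4)$tau, 1)
  expect_equal(kendall_tau_b(1:4, 4:1)$tau, -1)
  # 10 pairs: 8 concordant, 2 discordant
  expect_equal(kendall_tau_b(1:5, c(2, 1, 4, 3, 5))$tau, 0.6)
})

test_that("tau-b matches exhaustive pair enumeration for n <= 8 with ties", {
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(3:8, 1)
    x <- sample(1:4, n, replace = TRUE)   # ties likely
    y <- sample(1:4, n, replace = TRUE)
    orac <- oracle_tau_b(x, y)
    got <- suppressWarnings(kendall_tau_b(x, y)$tau)
    if (is.na(orac)) expect_true(is.na(got)) else expect_equal(got, orac)
    # agreement with the standard library implementation as well
    if (!is.na(orac))
      expect_equal(got, unname(stats::cor(x, y, method = "kendall")))
  }
})

test_that("tau-b is invariant under strictly monotone transforms", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    x <- rnorm(n); y <- rnorm(n)
    t1 <- kendall_tau_b(x, y)$tau
    expect_equal(kendall_tau_b(exp(x), y)$tau, t1)
    expect_equal(kendall_tau_b(x, 3 * y - 7)$tau, t1)
    expect_equal(kendall_tau_b(rank(x), y^3)$tau, t1)
  }
})

test_that("p-values: exact for small tie-free samples, tie-corrected normal otherwise", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  r <- kendall_tau_b(x, y)
  expect_equal(r$p_value,
               stats::cor.test(x, y, method = "kendall", exact = TRUE)$p.value)
  # large tie-free sample: matches the classic normal approximation
  set.seed(3); x2 <- rnorm(40); y2 <- x2 + rnorm(40)
  r2 <- kendall_tau_b(x2, y2)
  S <- r2$tau * choose(40, 2)
  z <- S / sqrt(40 * 39 * 85 / 18)
  expect_equal(r2$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-10)
  expect_lt(r2$p_value, 1e-4)
  # ties shrink the variance relative to the uncorrected formula
  x3 <- rep(1:5, 4); y3 <- x3 + rep(c(0, 1), 10)
  expect_lt(kendall_tau_b(x3, y3)$p_value, 1)
})

test_that("degenerate inputs give the undefined-correlation marker", {
  expect_warning(r <- kendall_tau_b(rep(1, 5), 1:5), "tied")
  expect_true(is.na(r$tau) && is.na(r$p_value))
  expect_error(kendall_tau_b(1:3, 1:4), "equal length")
  expect_error(kendall_tau_b(1, 1), "at least 2")
  # pairwise-complete: NA pairs dropped
  expect_equal(kendall_tau_b(c(1, 2, NA, 3), c(1, 2, 9, 3))$n, 3)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(8)
  tab <- data.frame(P1 = runif(20, 10, 60))
  tab$P2 <- 2 * tab$P1                 # monotone transform: tau 1
  tab$P3 <- runif(20, 0, 5); tab$P4 <- runif(20, 0, 3); tab$P5 <- runif(20, 0, 3)
  cm <- correlation_matrix(tab)
  expect_equal(cm$tau, t(cm$tau))
  expect_equal(unname(diag(cm$tau)), rep(1, 5))
  expect_equal(cm$tau["P1", "P2"], 1)
  expect_error(correlation_matrix(tab[1:2, ]), "insufficient")
  expect_error(correlation_matrix(tab[, 1:3]), "missing parameter columns")
})

test_that("independent columns show near-zero correlations at n = 60", {
  set.seed(42)
  tab <- data.frame(P1 = runif(60), P2 = runif(60), P3 = runif(60),
                    P4 = runif(60), P5 = runif(60))
  cm <- correlation_matrix(tab)
  off <- cm$tau[upper.tri(cm$tau)]
  expect_true(all(abs(off) < 0.3))
})

test_that("wild-type CV% is SD of means over mean of means", {
  ex <- make_experiments(c("WT_a", "WT_b", "WT_c"), c("01", "02", "03"),
                         rep("wildtype", 3),
                         matrix(rep(c(10, 20, 30), 5), 3, 5), sd = 0, n = 4)
  cv <- wildtype_cv(summarize_strains(ex))
  expect_equal(unname(cv["P1"]), 50)   # SD 10 / mean 20

  ex2 <- make_experiments(c("WT_a", "WT_b"), c("01", "02"),
                          rep("wildtype", 2),
                          matrix(25, 2, 5), sd = 0, n = 4)
  expect_equal(unname(wildtype_cv(summarize_strains(ex2))["P3"]), 0)
  expect_error(wildtype_cv(summarize_strains(ex2)[0, ]), "at least 2")
})

test_that("a generated 20% wild-type CV is recovered within 6 points", {
  tr <- generate_strain_table(n_wildtype_sets = 22, n_modified = 3,
                              baseline_mean = c(P1 = 5, P2 = 5, P3 = 5,
                                                P4 = 5, P5 = 5, P6 = 5,
                                                P7 = 5, P8 = 5),
                              baseline_cv = c(P1 = 0.2, P2 = 0.2, P3 = 0.2,
                                              P4 = 0.2, P5 = 0.2, P6 = 0.2,
                                              P7 = 0.2, P8 = 0.2),
                              group_sd = 0.3, seed = 2024)
  cv <- wildtype_cv(summarize_strains(tr$experiments))
  expect_lt(abs(cv[["P1"]] - 20), 6)
  expect_lt(abs(cv[["P4"]] - 20), 6)
})
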