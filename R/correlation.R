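#' Kendall's tau-b rank correlation
#'
#' Tau-b with the standard tie correction,
#' \deqn{\tau_b = (C - D) / \sqrt{(n_0 - n_1)(n_0 - n_2)},}
#' where \eqn{C} and \eqn{D} are the concordant and discordant pair counts,
#' \eqn{n_0 = n(n-1)/2} and \eqn{n_1, n_2} the tie terms of each argument.
#' The p-value uses the normal approximation with the tie-corrected variance
#' of \eqn{C - D}; for n <= 10 without ties the exact null distribution is
#' used instead. Incomplete pairs are dropped (pairwise-complete).
#'
#' An all-tied argument makes the denominator zero; the correlation is then
#' undefined and `NA` is returned for both tau and p.
#'
#' @param x,y numeric vectors of equal length (n >= 2 after NA removal).
#' @return list with `tau`, `p_value`, and `n` (complete pairs used).
#' @examples
#' kendall_tau_b(1:5, c(2, 1, 4, 3, 5))$tau  # 0.6
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)

  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- sign(x[pr[, 2]] - x[pr[, 1]])
  dy <- sign(y[pr[, 2]] - y[pr[, 1]])
  S <- sum(dx * dy)                       # C - D

  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) {
    warning("undefined correlation: an argument is completely tied")
    return(list(tau = NA_real_, p_value = NA_real_, n = n))
  }
  tau <- S / den

  no_ties <- n1 == 0 && n2 == 0
  if (n <= 10 && no_ties) {
    p <- stats::cor.test(x, y, method = "kendall", exact = TRUE)$p.value
  } else {
    # tie-corrected variance of S (Kendall 1970)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5)); vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v0 <- n * (n - 1) * (2 * n + 5)
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- if (n > 2)
      sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
        (9 * n * (n - 1) * (n - 2)) else 0
    vS <- (v0 - vt - vu) / 18 + v1 + v2
    p <- if (vS <= 0) NA_real_ else 2 * stats::pnorm(-abs(S) / sqrt(vS))
    p <- min(p, 1)
  }
  list(tau = tau, p_value = p, n = n)
}

#' Kendall tau-b correlation matrix across thrombus parameters
#'
#' Pairwise tau-b correlations (and p-values) between parameters over the
#' strains of a raw parameter table, as used to relate platelet adhesion,
#' aggregation and the thrombus scores to each other.
#'
#' @param records data.frame with one row per strain (or experiment) and the
#'   parameters as columns.
#' @param parameters columns to correlate.
#' @return list of two symmetric matrices, `tau` (unit diagonal) and
#'   `p_value` (diagonal `NA`), computed on pairwise-complete observations.
#' @export
correlation_matrix <- function(records, parameters = c("P1", "P2", "P3", "P4", "P5")) {
  missing_cols <- setdiff(parameters, names(records))
  if (length(missing_cols))
    stop("missing parameter columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  complete <- sum(stats::complete.cases(records[, parameters]))
  if (complete < 3)
    stop("insufficient data: fewer than 3 complete rows", call. = FALSE)
  k <- length(parameters)
  tau <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(tau) <- dimnames(p) <- list(parameters, parameters)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- kendall_tau_b(records[[parameters[i]]], records[[parameters[j]]])
    tau[i, j] <- tau[j, i] <- r$tau
    p[i, j] <- p[j, i] <- r$p_value
  }
  list(tau = tau, p_value = p)
}

#' Between-dataset coefficient of variation of wild-type means
#'
#' Consistency metric for the wild-type control datasets: per parameter, the
#' CV% of the per-dataset means, `100 * SD(means) / mean(means)`.
#'
#' @param summary long summary data.frame ([summarize_strains()]) restricted
#'   to (or containing) wild-type strains.
#' @param surface microspot to evaluate.
#' @return named vector of CV percentages, one per parameter present; `NA`
#'   (with warning) where the mean of means is zero.
#' @export
wildtype_cv <- function(summary, surface = "M1") {
  wt <- summary[summary$genotype_class == "wildtype" & summary$surface == surface, ]
  if (length(unique(wt$strain_id)) < 2)
    stop("need at least 2 wild-type datasets", call. = FALSE)
  out <- vapply(split(wt, wt$parameter), function(g) {
    m <- g$mean[!is.na(g$mean)]
    if (length(m) < 2) return(NA_real_)
    mu <- mean(m)
    if (mu == 0) { warning("zero mean: CV undefined"); return(NA_real_) }
    100 * stats::sd(m) / mu
  }, 0)
  out[order(names(out))]
}
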