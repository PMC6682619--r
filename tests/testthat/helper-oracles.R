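# Independent oracles used across the test suite. These deliberately use
# naive explicit algorithms (per-pixel loops, exhaustive pair counting,
# subset enumeration) so they share no code with the implementation.

# sliding min/max filter with an explicit footprint loop; outside-image
# positions are ignored (footprint restricted to the image)
oracle_rank_filter <- function(img, se, fun) {
  r <- (dim(se) - 1) / 2
  n <- nrow(img); m <- ncol(img)
  out <- img
  off <- which(se == 1, arr.ind = TRUE)
  off[, 1] <- off[, 1] - r[1] - 1
  off[, 2] <- off[, 2] - r[2] - 1
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ii <- i + off[, 1]; jj <- j + off[, 2]
    ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= m
    out[i, j] <- fun(img[cbind(ii[ok], jj[ok])])
  }
  out
}

oracle_dilate <- function(img, se) oracle_rank_filter(img, se, max)
oracle_erode <- function(img, se) oracle_rank_filter(img, se, min)
oracle_close <- function(img, se) oracle_erode(oracle_dilate(img, se), se)

# the full brightfield morphology sequence via the oracle filters
oracle_morph_chain <- function(px, cfg) {
  d1 <- EBImage::makeBrush(2 * cfg$large_diamond_radius_px + 1, "diamond")
  d2 <- EBImage::makeBrush(2 * cfg$medium_circle_radius_px + 1, "disc")
  d3 <- EBImage::makeBrush(2 * cfg$small_circle_radius_px + 1, "disc")
  oracle_dilate(oracle_close(oracle_close(px, d1), d2), d3)
}

# Kendall tau-b by exhaustive pair enumeration with explicit tie terms
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- (x[i] - x[j]) * (y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  ties <- function(v) sum(sapply(unique(v), function(u) {
    t <- sum(v == u); t * (t - 1) / 2
  }))
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - ties(x)) * (n0 - ties(y)))
  if (den == 0) return(NA_real_)
  (C - D) / den
}

# direct DFT band-split oracle: zero every Fourier coefficient whose radial
# frequency is at or below the cutoff, transform back
oracle_highpass <- function(px, cutoff_cycles_per_px) {
  d <- dim(px)
  fr <- (function(n) { k <- 0:(n - 1); ifelse(k <= n / 2, k, k - n) / n })
  f2 <- outer(fr(d[1])^2, fr(d[2])^2, `+`)
  ft <- stats::fft(px)
  ft[f2 <= cutoff_cycles_per_px^2] <- 0
  Re(stats::fft(ft, inverse = TRUE)) / length(px)
}

# density and k-core check of a cluster, recomputed from the raw edge list
oracle_cluster_stats <- function(graph, members) {
  el <- igraph::as_data_frame(graph, what = "edges")
  inside <- el$from %in% members & el$to %in% members
  ne <- sum(inside)
  nv <- length(members)
  dens <- if (nv < 2) 0 else 2 * ne / (nv * (nv - 1))
  # iterative pruning for the k-core of the member-induced subgraph
  kmax <- 0
  for (k in seq_len(nv)) {
    keep <- members
    repeat {
      deg <- table(factor(c(el$from[el$from %in% keep & el$to %in% keep],
                            el$to[el$from %in% keep & el$to %in% keep]),
                          levels = keep))
      drop <- names(deg)[deg < k]
      if (length(drop) == 0) break
      keep <- setdiff(keep, drop)
    }
    if (length(keep) > 0) kmax <- k else break
  }
  list(n_edges = ne, density = dens, score = dens * nv, max_core = kmax)
}

# small deterministic experiment table for comparative-stage tests
make_experiments <- function(strains, db, class, means, sd = 0, n = 4,
                             parameters = c("P1", "P2", "P3", "P4", "P5"),
                             seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_along(strains), function(i) {
    df <- data.frame(strain_id = rep(strains[i], n), database_id = db[i],
                     genotype_class = class[i], surface = "M1",
                     shear_rate_per_s = 1000, n_images = 3L)
    for (p in paste0("P", 1:8)) df[[p]] <- NA_real_
    for (j in seq_along(parameters))
      df[[parameters[j]]] <- pmax(0, stats::rnorm(n, means[i, j], sd))
    df
  })
  do.call(rbind, rows)
}

# hand-built delta_matrix for unit tests of downstream consumers
fake_delta_matrix <- function(delta, relevant) {
  stopifnot(identical(dim(delta), dim(relevant)))
  structure(list(delta = delta, composite_sd = delta * 0 + 1,
                 relevant = relevant,
                 filtered = ifelse(relevant, delta, 0),
                 anchors = NULL, meta = NULL, composite = "rms"),
            class = "delta_matrix")
}
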