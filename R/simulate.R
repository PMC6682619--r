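#' Synthetic brightfield thrombus image with exact ground truth
#'
#' Renders a flow-chamber-like brightfield frame: bright platelet discs
#' (radius 2-4 px) and larger multi-intensity aggregate blobs on a uniform
#' background, degraded by the three artifacts the quantification pipeline
#' targets - periodic vertical striping, a linear illumination gradient,
#' and additive Gaussian sensor noise. Ground-truth masks are returned and
#' the truth percentages are computed from the masks exactly, never
#' estimated.
#'
#' Amplitudes are expressed as fractions of the dynamic range. Platelet
#' contrast is +0.22 and aggregate contrast +0.40 to +0.50 of the range over
#' a 0.35 background, emulating enhanced-contrast CCD recordings in which
#' platelet material appears bright.
#'
#' @param n_platelets number of single platelet discs.
#' @param aggregate_count number of aggregate blobs.
#' @param aggregate_radius_px approximate aggregate radius.
#' @param stripe_amplitude striping amplitude (fraction of range).
#' @param stripe_period_px striping period in pixels.
#' @param illumination_amplitude peak-to-peak linear gradient amplitude
#'   (fraction of range).
#' @param noise_sd Gaussian noise SD (fraction of range).
#' @param width,height image size (>= 256 each).
#' @param bit_depth 8 or 16.
#' @param seed RNG seed; identical seeds give bit-identical images.
#' @return list of class `image_truth`: `image` ([gray_image()]),
#'   `platelet_mask`, `aggregate_mask` ([binary_mask()], aggregate subset of
#'   platelet), `true_sac_percent`, `true_aggregate_percent`, and the
#'   artifact parameters.
#' @export
generate_brightfield <- function(n_platelets = 300, aggregate_count = 4,
                                 aggregate_radius_px = 14,
                                 stripe_amplitude = 0.10, stripe_period_px = 7,
                                 illumination_amplitude = 0.15,
                                 noise_sd = 0.02,
                                 width = 256, height = 256, bit_depth = 8L,
                                 seed = 1L) {
  if (width < 256 || height < 256)
    stop("image must be at least 256 x 256", call. = FALSE)
  if (any(c(n_platelets, aggregate_count, stripe_amplitude,
            illumination_amplitude, noise_sd) < 0))
    stop("parameters must be non-negative", call. = FALSE)
  set.seed(seed)
  maxval <- 2^bit_depth - 1

  field <- matrix(0, height, width)       # object contrast (fraction units)
  plat <- matrix(FALSE, height, width)
  agg <- matrix(FALSE, height, width)

  # aggregates first: blobs of a few overlapping discs, brighter core
  for (i in seq_len(aggregate_count)) {
    placed <- FALSE
    for (try in 1:200) {
      cy <- sample.int(height - 2 * aggregate_radius_px, 1) + aggregate_radius_px
      cx <- sample.int(width - 2 * aggregate_radius_px, 1) + aggregate_radius_px
      blob <- matrix(FALSE, height, width)
      for (k in 1:5) {
        oy <- cy + sample(-aggregate_radius_px:aggregate_radius_px, 1) %/% 2
        ox <- cx + sample(-aggregate_radius_px:aggregate_radius_px, 1) %/% 2
        blob <- blob | disc_mask(height, width, oy, ox,
                                 round(aggregate_radius_px * stats::runif(1, 0.6, 0.9)))
      }
      if (!any(blob & dilate_mask(agg, 3))) { placed <- TRUE; break }
    }
    if (!placed) stop("placement error: could not place aggregate ", i, call. = FALSE)
    core <- dilate_mask(blob, -4)          # eroded interior, brighter
    field[blob] <- pmax(field[blob], 0.40)
    field[core & blob] <- 0.50
    agg <- agg | blob
  }

  # single platelets, non-overlapping (>= 2 px spacing), avoiding aggregates
  occupied <- dilate_mask(agg, 2)
  placed_n <- 0; attempts <- 0
  while (placed_n < n_platelets) {
    attempts <- attempts + 1
    if (attempts > 200 * max(n_platelets, 1))
      stop("placement error: could not place ", n_platelets,
           " non-overlapping platelets", call. = FALSE)
    r <- sample(2:4, 1)
    cy <- sample.int(height - 2 * r, 1) + r
    cx <- sample.int(width - 2 * r, 1) + r
    # check a spacing halo around the candidate within its local window only
    ys <- max(1, cy - r - 2):min(height, cy + r + 2)
    xs <- max(1, cx - r - 2):min(width, cx + r + 2)
    halo <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= (r + 2)^2
    if (any(occupied[ys, xs][halo])) next
    d <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
    idx <- which(d, arr.ind = TRUE)
    cells <- cbind(ys[idx[, 1]], xs[idx[, 2]])
    field[cells] <- 0.22
    plat[cells] <- TRUE
    occupied[cells] <- TRUE
    placed_n <- placed_n + 1
  }
  plat <- plat | agg

  cols <- matrix(seq_len(width) - 1, height, width, byrow = TRUE)
  img <- 0.35 + field +
    stripe_amplitude / 2 * sin(2 * pi * cols / stripe_period_px) +
    illumination_amplitude * (cols / (width - 1) - 0.5) +
    stats::rnorm(height * width, 0, noise_sd)
  px <- round(clip_intensity(img * maxval, bit_depth))

  structure(list(
    image = gray_image(px, bit_depth = bit_depth, channel = "brightfield"),
    platelet_mask = binary_mask(plat),
    aggregate_mask = binary_mask(agg),
    true_sac_percent = 100 * mean(plat),
    true_aggregate_percent = 100 * mean(agg),
    params = list(n_platelets = n_platelets, aggregate_count = aggregate_count,
                  stripe_amplitude = stripe_amplitude,
                  stripe_period_px = stripe_period_px,
                  illumination_amplitude = illumination_amplitude,
                  noise_sd = noise_sd),
    seed = seed), class = "image_truth")
}

disc_mask <- function(h, w, cy, cx, r) {
  y <- matrix(seq_len(h), h, w); x <- matrix(seq_len(w), h, w, byrow = TRUE)
  (y - cy)^2 + (x - cx)^2 <= r^2
}

# signed dilation helper: r > 0 dilate, r < 0 erode, square structuring element
dilate_mask <- function(m, r) {
  if (r == 0 || !any(m)) return(m)
  k <- EBImage::makeBrush(2L * abs(r) + 1L, "box")
  if (r > 0) EBImage::dilate(m * 1, k) > 0 else EBImage::erode(m * 1, k) > 0
}

#' Synthetic fluorescence channel with exact ground truth
#'
#' Marks a requested fraction of the platelet-mask pixels as stained,
#' growing contiguous patches inside the mask so staining is spatially
#' coherent (as for PS exposure / P-selectin / JON-A labels). The positive
#' pixel count is exactly `round(positive_fraction * mask area)`, so the
#' truth %SAC equals `positive_fraction x platelet %SAC` up to that
#' rounding.
#'
#' @param platelet_mask a [binary_mask()] (e.g. from
#'   [generate_brightfield()]).
#' @param positive_fraction fraction of platelet pixels stained, in [0, 1].
#' @param noise_sd Gaussian noise SD (fraction of range).
#' @param channel fluorescence channel label.
#' @inheritParams generate_brightfield
#' @return list of class `image_truth` with `image`, `positive_mask`,
#'   `true_sac_percent`.
#' @export
generate_fluorescence <- function(platelet_mask, positive_fraction,
                                  noise_sd = 0.02, bit_depth = 8L, seed = 1L,
                                  channel = "annexinA5") {
  stopifnot(inherits(platelet_mask, "binary_mask"))
  if (positive_fraction < 0 || positive_fraction > 1)
    stop("invalid input: positive_fraction must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  m <- platelet_mask$pixels
  quota <- round(positive_fraction * sum(m))
  pos <- matrix(FALSE, nrow(m), ncol(m))
  remaining <- m
  while (sum(pos) < quota) {
    seeds <- which(remaining)
    if (length(seeds) == 0) break
    patch <- matrix(FALSE, nrow(m), ncol(m))
    patch[seeds[sample.int(length(seeds), 1)]] <- TRUE
    repeat {                      # grow the patch inside the mask
      grown <- dilate_mask(patch, 1) & remaining
      if (sum(pos) + sum(grown) >= quota || all(grown == patch)) {
        ring <- which(grown & !patch)     # trim the last ring, row-major
        need <- quota - sum(pos) - sum(patch)
        if (need > 0 && length(ring) > 0)
          patch[ring[seq_len(min(need, length(ring)))]] <- TRUE
        break
      }
      patch <- grown
    }
    pos <- pos | patch
    remaining <- remaining & !pos
  }
  maxval <- 2^bit_depth - 1
  img <- 0.04 + 0.55 * pos + stats::rnorm(length(m), 0, noise_sd)
  px <- round(clip_intensity(img * maxval, bit_depth))
  structure(list(
    image = gray_image(px, bit_depth = bit_depth, channel = channel),
    positive_mask = binary_mask(pos),
    true_sac_percent = 100 * sum(pos) / length(m),
    params = list(positive_fraction = positive_fraction, noise_sd = noise_sd),
    seed = seed), class = "image_truth")
}

#' Synthetic multi-strain parameter table with planted effects
#'
#' Emulates the statistical structure of the comparative assay: wild-type
#' datasets with between-dataset baseline variation, modified strains paired
#' to them, and per-animal replicate noise. Values are drawn on the 0-10
#' scaled axis (normal, truncated to the axis) and converted to each
#' parameter's raw range, so the pipeline's scaling machinery is exercised
#' end to end. Planted per-parameter effects (scaled units) are stored
#' exactly as used.
#'
#' Default baselines and spreads emulate the wild-type consistency of the
#' assay (between-dataset CV about 24% for the coverage parameters P1-P2 and
#' about 11% for the visual scores P3-P5).
#'
#' @param n_wildtype_sets number of wild-type control datasets.
#' @param n_modified number of modified strains (each paired to a wild-type
#'   dataset, cycling).
#' @param planted_effects numeric matrix `n_modified x length(parameters)`
#'   of effects on the scaled axis (or a single number recycled; default 0).
#' @param group_sd replicate SD on the scaled axis.
#' @param n_per_group animals per modified group.
#' @param n_wildtype_per_group animals per wild-type dataset.
#' @param parameters parameter subset to simulate.
#' @param baseline_mean,baseline_cv named per-parameter baseline means
#'   (scaled units) and between-dataset CVs.
#' @param enforce_inclusion check the assay's minimum-n rule (>= 3 modified,
#'   >= 4 wild-type) and raise an exclusion error when violated.
#' @param surface microspot label for the generated rows.
#' @param seed RNG seed.
#' @return list of class `strain_table_truth`: `experiments` (tidy table as
#'   consumed by [summarize_strains()]), `planted` (effects matrix, strains
#'   x parameters), `baselines`, `group_sd`, `anchors` (the generator's
#'   scaled axis: each parameter's range maximum, named by heatmap column -
#'   pass to [scale_strain_means()] to recover planted effects on the exact
#'   axis they were planted on), `seed`.
#' @export
generate_strain_table <- function(n_wildtype_sets = 22, n_modified = 38,
                                  planted_effects = 0, group_sd = 1,
                                  n_per_group = 4, n_wildtype_per_group = 4,
                                  parameters = c("P1", "P2", "P3", "P4", "P5"),
                                  baseline_mean = c(P1 = 5.5, P2 = 5, P3 = 6,
                                                    P4 = 5.5, P5 = 5.5, P6 = 5,
                                                    P7 = 5, P8 = 5),
                                  baseline_cv = c(P1 = 0.24, P2 = 0.24,
                                                  P3 = 0.11, P4 = 0.11,
                                                  P5 = 0.11, P6 = 0.2,
                                                  P7 = 0.2, P8 = 0.2),
                                  enforce_inclusion = TRUE, surface = "M1",
                                  seed = 1L) {
  if (enforce_inclusion) {
    if (n_per_group < 3)
      stop("exclusion: modified groups require n >= 3 animals (got ",
           n_per_group, ")", call. = FALSE)
    if (n_wildtype_per_group < 4)
      stop("exclusion: wild-type groups require n >= 4 animals (got ",
           n_wildtype_per_group, ")", call. = FALSE)
  }
  np <- length(parameters)
  eff <- matrix(planted_effects, n_modified, np,
                dimnames = list(NULL, parameters))
  set.seed(seed)

  rng <- load_table2_ranges()
  range_max <- stats::setNames(rng$range_max, rng$parameter)
  # %SAC parameters live on their observed-range axis; convert units -> raw
  to_raw <- function(u, p) u / 10 * range_max[[p]]

  dbs <- sprintf("%02d", seq_len(n_wildtype_sets))
  base <- matrix(0, n_wildtype_sets, np, dimnames = list(dbs, parameters))
  for (p in parameters)
    base[, p] <- rtruncnorm(n_wildtype_sets, baseline_mean[[p]],
                            baseline_cv[[p]] * baseline_mean[[p]], 0.5, 9.9)

  mod_db <- rep(dbs, length.out = n_modified)
  mod_mean <- base[mod_db, , drop = FALSE] + eff
  if (any(mod_mean < 0 | mod_mean > 10))
    stop("invalid input: planted mean outside the parameter range", call. = FALSE)

  rows <- list()
  emit <- function(strain, db, cls, means) {
    nrep <- if (cls == "wildtype") n_wildtype_per_group else n_per_group
    vals <- sapply(parameters, function(p)
      to_raw(rtruncnorm(nrep, means[[p]], group_sd, 0, 10), p))
    vals <- matrix(vals, nrow = nrep, dimnames = list(NULL, parameters))
    df <- data.frame(strain_id = rep(strain, nrep), database_id = db,
                     genotype_class = cls, surface = surface,
                     shear_rate_per_s = 1000, n_images = 3L,
                     stringsAsFactors = FALSE)
    for (p in parameter_names()) df[[p]] <- if (p %in% parameters) vals[, p] else NA_real_
    df
  }
  for (i in seq_len(n_wildtype_sets))
    rows[[length(rows) + 1L]] <- emit(paste0("WT_", dbs[i]), dbs[i], "wildtype",
                                      as.list(base[i, ]))
  strains <- sprintf("G%02d", seq_len(n_modified))
  rownames(eff) <- strains
  for (i in seq_len(n_modified))
    rows[[length(rows) + 1L]] <- emit(strains[i], mod_db[i], "modified",
                                      as.list(mod_mean[i, ]))
  anchors <- stats::setNames(range_max[parameters],
                             paste(surface, parameters, sep = "."))
  structure(list(experiments = do.call(rbind, rows), planted = eff,
                 baselines = base, group_sd = group_sd, anchors = anchors,
                 n_per_group = n_per_group, seed = seed),
            class = "strain_table_truth")
}

# inverse-CDF truncated normal: deterministic under set.seed
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Planted-partition interaction graph
#'
#' Stochastic block model with dense blocks (`p_in`) and sparse
#' between-block wiring (`p_out`), edge confidences uniform in [0.40,
#' 0.99], and exact membership truth - the benchmark for the MCODE
#' clustering.
#'
#' @param block_sizes integer vector of block sizes.
#' @param p_in,p_out within-/between-block edge probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param seed RNG seed.
#' @return list with `graph` (igraph, vertex attr `block`, edge attr
#'   `confidence`) and `membership` (named integer vector).
#' @export
generate_planted_cluster_graph <- function(block_sizes = c(8, 8), p_in = 0.9,
                                           p_out = 0.05, seed = 1L) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1))
    stop("invalid input: need 0 <= p_out < p_in <= 1", call. = FALSE)
  set.seed(seed)
  k <- length(block_sizes)
  pref <- matrix(p_out, k, k); diag(pref) <- p_in
  g <- igraph::sample_sbm(sum(block_sizes), pref, block_sizes)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(sum(block_sizes)))
  member <- rep(seq_len(k), block_sizes)
  igraph::V(g)$block <- member
  igraph::E(g)$confidence <- stats::runif(igraph::ecount(g), 0.40, 0.99)
  list(graph = g, membership = stats::setNames(member, igraph::V(g)$name))
}
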