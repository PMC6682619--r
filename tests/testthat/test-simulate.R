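test_that("brightfield generation is seed-deterministic with exact truth", {
  a <- generate_brightfield(seed = 17)
  b <- generate_brightfield(seed = 17)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$platelet_mask$pixels, b$platelet_mask$pixels)

  # truth percentages are mask arithmetic, exactly
  expect_equal(a$true_sac_percent, 100 * mean(a$platelet_mask$pixels))
  expect_equal(a$true_aggregate_percent, 100 * mean(a$aggregate_mask$pixels))
  # aggregates are a subset of the platelet mask
  expect_true(all(a$platelet_mask$pixels[a$aggregate_mask$pixels]))
})

test_that("an object-free frame has zero truth and a near-zero estimate", {
  tr <- generate_brightfield(n_platelets = 0, aggregate_count = 0, seed = 2)
  expect_equal(tr$true_sac_percent, 0)
  q <- quantify_brightfield(tr$image)
  expect_lt(q$sac_percent, 1)
})

test_that("impossible placements raise a placement error", {
  expect_error(generate_brightfield(n_platelets = 3000, seed = 1),
               "placement error")
  expect_error(generate_brightfield(width = 128, height = 128), "256")
  expect_error(generate_brightfield(noise_sd = -0.1), "non-negative")
})

test_that("fluorescence truth equals fraction x platelet coverage", {
  tr <- generate_brightfield(seed = 6)
  f0 <- generate_fluorescence(tr$platelet_mask, 0, seed = 1)
  expect_equal(f0$true_sac_percent, 0)
  expect_true(all(f0$positive_mask$pixels == FALSE))

  f1 <- generate_fluorescence(tr$platelet_mask, 1, seed = 1)
  expect_equal(f1$true_sac_percent, tr$true_sac_percent)

  f5 <- generate_fluorescence(tr$platelet_mask, 0.5, seed = 1)
  expect_equal(f5$true_sac_percent, 0.5 * tr$true_sac_percent,
               tolerance = 100 / length(tr$platelet_mask$pixels))
  # positives lie inside the platelet mask
  expect_true(all(tr$platelet_mask$pixels[f5$positive_mask$pixels]))
  expect_error(generate_fluorescence(tr$platelet_mask, 1.2), "\\[0, 1\\]")
})

test_that("strain tables are deterministic and store planted effects exactly", {
  eff <- matrix(0, 3, 5); eff[2, 1] <- -2.5
  flat <- c(P1 = 0, P2 = 0, P3 = 0, P4 = 0, P5 = 0)
  a <- generate_strain_table(n_wildtype_sets = 3, n_modified = 3,
                             planted_effects = eff, baseline_cv = flat,
                             seed = 4)
  b <- generate_strain_table(n_wildtype_sets = 3, n_modified = 3,
                             planted_effects = eff, baseline_cv = flat,
                             seed = 4)
  expect_identical(a$experiments, b$experiments)
  expect_equal(unname(a$planted[2, "P1"]), -2.5)
  # values live on each parameter's published raw range
  expect_true(all(a$experiments$P1 <= 93.67))
  expect_true(all(a$experiments$P3 <= 5))
})

test_that("the generator enforces the inclusion rule and valid planted means", {
  expect_error(generate_strain_table(n_per_group = 2), "exclusion")
  expect_error(generate_strain_table(n_wildtype_per_group = 3), "exclusion")
  expect_silent(generate_strain_table(n_wildtype_sets = 2, n_modified = 2,
                                      n_per_group = 2,
                                      enforce_inclusion = FALSE, seed = 1))
  expect_error(generate_strain_table(n_wildtype_sets = 2, n_modified = 2,
                                     planted_effects = 9, seed = 1),
               "outside the parameter range")
})

test_that("planted-partition graphs honor their parameters", {
  pg <- generate_planted_cluster_graph(c(5, 5), 1, 0, seed = 1)
  g <- pg$graph
  expect_equal(igraph::ecount(g), 2 * choose(5, 2))   # two disjoint cliques
  comp <- igraph::components(g)
  expect_equal(comp$no, 2)
  expect_true(all(igraph::E(g)$confidence >= 0.40 &
                    igraph::E(g)$confidence <= 0.99))

  a <- generate_planted_cluster_graph(c(8, 8), 0.9, 0.05, seed = 9)
  b <- generate_planted_cluster_graph(c(8, 8), 0.9, 0.05, seed = 9)
  expect_identical(igraph::as_edgelist(a$graph), igraph::as_edgelist(b$graph))
  expect_error(generate_planted_cluster_graph(c(4, 4), 0.5, 0.6), "p_out < p_in")
})

test_that("null planted effects produce unbiased deltas over many seeds", {
  ds <- vapply(1:60, function(k) {
    tr <- generate_strain_table(n_wildtype_sets = 2, n_modified = 2,
                                planted_effects = 0, group_sd = 1,
                                seed = 400 + k)
    dm <- build_delta_matrix(
      scale_strain_means(summarize_strains(tr$experiments),
                         anchors = tr$anchors))
    mean(dm$delta)
  }, 0)
  expect_lt(abs(mean(ds)), 0.2)
})

test_that("end-to-end %SAC recovery across artifact amplitudes", {
  set.seed(60)
  for (rep in 1:5) {
    tr <- generate_brightfield(
      n_platelets = sample(100:350, 1), aggregate_count = sample(0:4, 1),
      stripe_amplitude = runif(1, 0, 0.15),
      illumination_amplitude = runif(1, 0, 0.20),
      noise_sd = runif(1, 0.01, 0.03), seed = 600 + rep)
    q <- quantify_brightfield(tr$image)
    expect_lt(abs(q$sac_percent - tr$true_sac_percent), 2)
  }
})
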