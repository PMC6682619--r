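write_edge_file <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("node1\tnode2\tcombined_score", rows), f)
  f
}

test_that("edge lists are deduplicated, filtered and dialect-detected", {
  f <- write_edge_file(c("A\tB\t900", "B\tA\t850", "A\tC\t700"))
  g <- load_edges(f)
  expect_equal(igraph::ecount(g), 2)
  # highest confidence kept for the duplicate pair
  eAB <- igraph::E(g)[igraph::V(g)["A"] %--% igraph::V(g)["B"]]
  expect_equal(eAB$confidence, 0.9)

  # integer dialect: 399/1000 falls below the 0.40 cutoff
  f2 <- write_edge_file(c("A\tB\t399", "A\tC\t400"))
  g2 <- load_edges(f2)
  expect_equal(igraph::ecount(g2), 1)

  # float dialect passes through unchanged
  f3 <- write_edge_file(c("A\tB\t0.95", "A\tC\t0.2"))
  g3 <- load_edges(f3)
  expect_equal(igraph::ecount(g3), 1)
  expect_equal(igraph::E(g3)$confidence, 0.95)

  f4 <- write_edge_file(character(0))
  expect_warning(g4 <- load_edges(f4), "empty")
  expect_equal(igraph::vcount(g4), 0)

  expect_error(load_edges(write_edge_file("A\tB\tnot_a_number")),
               "parse error.*line 2")
  expect_error(load_edges(write_edge_file(c("A\tB\t500", "A\tC\t-2"))),
               "parse error.*line 3")
})

test_that("confidence filtering is monotone and classes are assigned", {
  f <- write_edge_file(c("Gp6\tSyk\t999", "Gp6\tFoo\t450", "Foo\tBar\t410"))
  e1 <- igraph::ecount(load_edges(f, 0.40))
  e2 <- igraph::ecount(load_edges(f, 0.60))
  e3 <- igraph::ecount(load_edges(f, 0.95))
  expect_true(e1 >= e2 && e2 >= e3)
  g <- load_edges(f)
  expect_equal(sort(igraph::V(g)$name[igraph::V(g)$class == "core"]),
               c("Gp6", "Syk"))
})

test_that("mcode finds K5 as one perfect cluster and ignores the chain", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_ring(3, circular = FALSE))
  igraph::V(g)$name <- letters[1:8]
  cl <- mcode(g)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members, letters[1:5])
  expect_equal(cl[[1]]$score, 5)      # density 1 x 5 nodes
  expect_equal(cl[[1]]$n_edges, 10L)

  # brute-force check: no subset of this 8-node graph scores higher than K5
  nodes <- letters[1:8]
  best <- 0
  for (k in 3:8) {
    combs <- utils::combn(nodes, k)
    for (i in seq_len(ncol(combs)))
      best <- max(best, oracle_cluster_stats(g, combs[, i])$score)
  }
  expect_equal(cl[[1]]$score, best)
})

test_that("edgeless graphs yield no clusters; non-simple graphs error", {
  g <- igraph::make_empty_graph(5, directed = FALSE)
  expect_length(mcode(g), 0)
  gm <- igraph::make_graph(c(1, 2, 1, 2), directed = FALSE)
  expect_error(mcode(gm), "simple")
})

test_that("every cluster's score and k-core survive independent recomputation", {
  set.seed(12)
  for (rep in 1:5) {
    g <- igraph::sample_gnp(30, 0.18)
    igraph::V(g)$name <- sprintf("v%02d", 1:30)
    for (cl in mcode(g)) {
      st <- oracle_cluster_stats(g, cl$members)
      expect_equal(cl$score, st$score)
      expect_equal(cl$n_edges, st$n_edges)
      expect_gte(st$max_core, 2)      # k_core filter verified independently
    }
  }
})

test_that("mcode output is invariant under node relabeling", {
  set.seed(30)
  g <- igraph::sample_gnp(24, 0.25)
  igraph::V(g)$name <- sprintf("a%02d", 1:24)
  cl1 <- mcode(g)
  perm <- sample(24)
  g2 <- igraph::permute(g, perm)
  cl2 <- mcode(g2)
  sets1 <- lapply(cl1, `[[`, "members")
  sets2 <- lapply(cl2, `[[`, "members")
  expect_equal(lapply(sets1, sort), lapply(sets2, sort))
  expect_equal(vapply(cl1, `[[`, 0, "score"), vapply(cl2, `[[`, 0, "score"))
})

test_that("planted blocks are recovered at a fixed seed", {
  pg <- generate_planted_cluster_graph(c(8, 8), 0.9, 0.05, seed = 5)
  cl <- mcode(pg$graph)
  top <- cl[seq_len(min(2, length(cl)))]
  for (b in 1:2) {
    truth <- names(pg$membership)[pg$membership == b]
    hit <- max(vapply(top, function(c2)
      length(intersect(c2$members, truth)), 0))
    expect_gte(hit, 7)
  }
})

test_that("effects annotate core nodes, novel nodes stay neutral", {
  eff <- matrix(0, 2, 5); eff[1, 2:5] <- -3
  tr <- generate_strain_table(n_wildtype_sets = 2, n_modified = 2,
                              planted_effects = eff, group_sd = 0.2,
                              baseline_cv = c(P1 = 0, P2 = 0, P3 = 0,
                                              P4 = 0, P5 = 0), seed = 2)
  dm <- build_delta_matrix(scale_strain_means(summarize_strains(tr$experiments),
                                              anchors = tr$anchors))
  # map the generated strain ids onto gene symbols incl. a dual deficiency
  rn <- c("Gp6/Clec1b", "Rac1")
  rownames(dm$delta) <- rownames(dm$relevant) <- rownames(dm$filtered) <- rn

  f <- write_edge_file(c("Gp6\tClec1b\t900", "Gp6\tRac1\t800",
                         "Novelx\tGp6\t500", "Missing\tRac1\t700"))
  g <- load_edges(f, core_genes = c("Gp6", "Clec1b", "Rac1", "Missing"))
  ann <- annotate_effects(g, dm, mode = "signature")

  expect_lt(ann$effect[ann$node == "Gp6"], -10)
  expect_equal(ann$effect[ann$node == "Gp6"], ann$effect[ann$node == "Clec1b"])
  expect_equal(ann$direction[ann$node == "Gp6"], "reducing")
  expect_equal(ann$effect[ann$node == "Novelx"], 0)
  expect_equal(ann$direction[ann$node == "Novelx"], "neutral")
  expect_equal(attr(ann, "unmatched"), "Missing")
})

test_that("network export writes graphml, sif and tables", {
  pg <- generate_planted_cluster_graph(c(6, 6), 1, 0, seed = 3)
  igraph::V(pg$graph)$class <- "novel"
  cl <- mcode(pg$graph)
  out <- tempfile()
  ann <- data.frame(node = igraph::V(pg$graph)$name, class = "novel",
                    effect = 0, direction = "neutral",
                    strain_id = NA_character_)
  paths <- export_network(pg$graph, ann, cl, out_dir = out)
  expect_true(all(file.exists(paths)))
  sif <- readLines(paths[["sif"]])
  expect_equal(length(sif), igraph::ecount(pg$graph))
  clust <- utils::read.csv(paths[["clusters"]])
  expect_equal(nrow(clust), length(cl))
})
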