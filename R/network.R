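#' Load a confidence-weighted protein-interaction edge list
#'
#' Reads a STRING-style TSV with columns `node1`, `node2`, `combined_score`
#' into an undirected [igraph][igraph::igraph-package] graph. Both score
#' dialects are accepted: integer 0-1000 (any score > 1 triggers division by
#' 1000) and float 0-1. Self-loops are dropped, duplicate pairs are collapsed
#' (keeping the highest confidence), and edges below `min_confidence` are
#' removed. Node class defaults to `"core"` for symbols in `core_genes` and
#' `"novel"` otherwise.
#'
#' @param path TSV file path.
#' @param min_confidence minimum combined score (0-1 scale) to keep an edge.
#' @param core_genes character vector of seed gene symbols (defaults to the
#'   packaged strain table's genes).
#' @return an undirected simple `igraph` with edge attribute `confidence`
#'   and vertex attribute `class`.
#' @export
load_edges <- function(path, min_confidence = 0.40, core_genes = NULL) {
  if (!file.exists(path)) stop("no such edge file: ", path, call. = FALSE)
  tab <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                  error = function(e) stop("parse error: ", conditionMessage(e),
                                           call. = FALSE))
  if (nrow(tab) == 0) {
    warning("empty edge file: returning an empty graph")
    return(igraph::make_empty_graph(directed = FALSE))
  }
  req <- c("node1", "node2", "combined_score")
  if (!all(req %in% names(tab)))
    stop("parse error: expected columns ", paste(req, collapse = ", "), call. = FALSE)
  sc <- suppressWarnings(as.numeric(tab$combined_score))
  bad <- which(is.na(sc) | !nzchar(tab$node1) | !nzchar(tab$node2))
  if (length(bad))
    stop("parse error: malformed row at line ", bad[1] + 1L, call. = FALSE)
  neg <- which(sc < 0)
  if (length(neg))
    stop("parse error: negative score at line ", neg[1] + 1L, call. = FALSE)
  if (any(sc > 1)) sc <- sc / 1000       # STRING integer dialect

  keep <- sc >= min_confidence & tab$node1 != tab$node2
  tab <- tab[keep, ]; sc <- sc[keep]
  # collapse duplicate unordered pairs, keeping the highest confidence
  key <- ifelse(tab$node1 < tab$node2, paste(tab$node1, tab$node2),
                paste(tab$node2, tab$node1))
  ord <- order(key, -sc)
  first <- !duplicated(key[ord])
  tab <- tab[ord, ][first, ]; sc <- sc[ord][first]

  g <- igraph::graph_from_data_frame(
    data.frame(from = tab$node1, to = tab$node2, confidence = sc),
    directed = FALSE)
  if (is.null(core_genes))
    core_genes <- unlist(strsplit(load_table1_fixture()$gene, "/", fixed = TRUE))
  igraph::V(g)$class <- ifelse(igraph::V(g)$name %in% core_genes, "core", "novel")
  g
}

#' MCODE molecular-complex detection
#'
#' Self-contained implementation of the MCODE graph-clustering algorithm.
#' Stage 1 weights every vertex by the density of the highest k-core of its
#' closed neighborhood multiplied by that core number (vertices below
#' `degree_cutoff` score 0). Stage 2 grows complexes outward from the
#' highest-weighted unvisited seed, including neighbors whose weight is at
#' least `seed_weight * (1 - node_score_cutoff)`, to at most `max_depth`
#' from the seed; a vertex can belong to only one complex. Post-processing
#' applies fluff, then the haircut (reduce each complex to its 2-core), and
#' discards complexes that do not contain a `k_core`-core.
#'
#' Cluster score is density x node count
#' (`2 * n_edges / (n_nodes * (n_nodes - 1)) * n_nodes`). Clusters are
#' returned sorted by score descending, ties by size then seed symbol; all
#' tie-breaks are lexicographic on vertex names, so output is deterministic
#' and invariant under node relabeling.
#'
#' @param graph a simple undirected `igraph`.
#' @param degree_cutoff minimum degree for a vertex to be weighted.
#' @param node_score_cutoff inclusion tolerance relative to the seed weight.
#' @param k_core minimum core a complex must contain.
#' @param max_depth maximum distance from the seed.
#' @param haircut reduce complexes to their 2-core (applied after fluff, so
#'   fluffed-in contaminants that attach by a single edge are removed again).
#' @param fluff expand each complex by one neighbor shell, adding neighbors
#'   whose closed-neighborhood density exceeds `fluff_density`. Fluffed
#'   vertices may belong to several complexes. Without fluff, members whose
#'   weight falls just below the seed-relative cutoff (typically boundary
#'   vertices of a dense module) are permanently lost to their complex, which
#'   measurably hurts recovery of planted modules; fluff re-admits them and
#'   is therefore on by default.
#' @param fluff_density closed-neighborhood density threshold for fluff.
#' @return list of clusters, each a list with `members` (sorted symbols),
#'   `seed`, `score`, `n_nodes`, `n_edges`, `density`.
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::V(g)$name <- letters[1:5]
#' mcode(g)[[1]]$score  # 5: density 1 x 5 nodes
#' @export
mcode <- function(graph, degree_cutoff = 2, node_score_cutoff = 0.2,
                  k_core = 2, max_depth = 100, haircut = TRUE, fluff = TRUE,
                  fluff_density = 0.1) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) graph <- igraph::as_undirected(graph, "collapse")
  if (!igraph::is_simple(graph))
    stop("invalid input: graph must be simple (no loops or multi-edges)",
         call. = FALSE)
  n <- igraph::vcount(graph)
  if (n == 0 || igraph::ecount(graph) == 0) return(list())
  if (is.null(igraph::V(graph)$name))
    igraph::V(graph)$name <- as.character(seq_len(n))
  nms <- igraph::V(graph)$name

  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  deg <- igraph::degree(graph)

  w <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] < degree_cutoff) next
    nb <- c(v, as.integer(adj[[v]]))
    sub <- igraph::induced_subgraph(graph, nb)
    core <- igraph::coreness(sub)
    k <- max(core)
    if (k == 0) next
    hk <- igraph::induced_subgraph(sub, which(core >= k))
    w[v] <- k * graph_density(hk)
  }

  # seeds in decreasing weight, lexicographic names for ties
  seed_order <- order(-w, nms)
  visited <- logical(n)
  clusters <- list()
  for (s in seed_order) {
    if (visited[s] || w[s] <= 0) next
    thr <- w[s] * (1 - node_score_cutoff)
    members <- s; visited[s] <- TRUE
    frontier <- s; depth <- 0
    while (length(frontier) && depth < max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(adj[[v]])) {
          if (!visited[u] && w[u] >= thr) {
            visited[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- sort(nxt)
      depth <- depth + 1
    }
    cl <- finalize_cluster(graph, members, seed = s, k_core = k_core,
                           haircut = haircut, fluff = fluff,
                           fluff_density = fluff_density)
    if (!is.null(cl)) clusters[[length(clusters) + 1L]] <- cl
  }
  ord <- order(-vapply(clusters, `[[`, 0, "score"),
               -vapply(clusters, `[[`, 0L, "n_nodes"),
               vapply(clusters, `[[`, "", "seed"))
  clusters[ord]
}

finalize_cluster <- function(graph, members, seed, k_core, haircut, fluff,
                             fluff_density) {
  nms <- igraph::V(graph)$name
  if (fluff) {
    extra <- integer(0)
    for (v in members) {
      for (u in as.integer(igraph::neighbors(graph, v))) {
        if (u %in% members || u %in% extra) next
        nb <- c(u, as.integer(igraph::neighbors(graph, u)))
        if (graph_density(igraph::induced_subgraph(graph, nb)) > fluff_density)
          extra <- c(extra, u)
      }
    }
    members <- c(members, extra)
  }
  sub <- igraph::induced_subgraph(graph, members)
  core <- igraph::coreness(sub)
  if (haircut) {
    keep <- core >= 2
    if (!any(keep)) return(NULL)
    sub <- igraph::induced_subgraph(sub, which(keep))
    core <- igraph::coreness(sub)
  }
  if (max(core) < k_core) return(NULL)   # must contain a k_core-core
  nv <- as.integer(igraph::vcount(sub))
  ne <- as.integer(igraph::ecount(sub))
  dens <- graph_density(sub)
  list(members = sort(igraph::V(sub)$name), seed = nms[seed],
       score = dens * nv, n_nodes = nv, n_edges = ne, density = dens)
}

graph_density <- function(g) {
  nv <- igraph::vcount(g)
  if (nv < 2) return(0)
  2 * igraph::ecount(g) / (nv * (nv - 1))
}

#' Annotate network nodes with thrombus effect sizes
#'
#' Attaches the per-strain relevance-filtered effect (thrombus signature
#' P2-P5, or platelet adhesion P1, at the given surface) to the core nodes
#' of an interaction graph; novel nodes receive a neutral attribute (0,
#' direction `"neutral"`). Strains targeting several genes (symbols joined
#' by "/") annotate each gene node with the same effect. Core nodes with no
#' matching strain are reported in the `unmatched` attribute, not an error.
#'
#' @param graph graph from [load_edges()] (vertex attribute `class`).
#' @param dm a [build_delta_matrix()] result with columns for `surface`.
#' @param mode `"signature"` (P2-P5) or `"adhesion"` (P1).
#' @param surface microspot whose deltas are used.
#' @return data.frame (`node`, `class`, `effect`, `direction`, `strain_id`)
#'   suitable for GraphML/SIF export, with attribute `unmatched`.
#' @export
annotate_effects <- function(graph, dm, mode = c("signature", "adhesion"),
                             surface = "M1") {
  mode <- match.arg(mode)
  stopifnot(igraph::is_igraph(graph), inherits(dm, "delta_matrix"))
  pars <- if (mode == "signature") c("P2", "P3", "P4", "P5") else "P1"
  eff <- effect_sum(dm, parameters = pars, surface = surface)

  gene_of <- strsplit(names(eff), "/", fixed = TRUE)
  gene_map <- data.frame(gene = unlist(gene_of),
                         strain_id = rep(names(eff), lengths(gene_of)),
                         effect = rep(unname(eff), lengths(gene_of)),
                         stringsAsFactors = FALSE)
  # a gene hit by several strains keeps the largest-magnitude effect
  gene_map <- gene_map[order(gene_map$gene, -abs(gene_map$effect)), ]
  gene_map <- gene_map[!duplicated(gene_map$gene), ]

  nodes <- igraph::V(graph)$name
  cls <- igraph::V(graph)$class
  if (is.null(cls)) cls <- rep("novel", length(nodes))
  m <- match(nodes, gene_map$gene)
  effect <- ifelse(cls == "core" & !is.na(m), gene_map$effect[m], 0)
  strain <- ifelse(cls == "core" & !is.na(m), gene_map$strain_id[m], NA_character_)
  out <- data.frame(node = nodes, class = cls, effect = effect,
                    direction = ifelse(effect < 0, "reducing",
                                       ifelse(effect > 0, "enhancing", "neutral")),
                    strain_id = strain, stringsAsFactors = FALSE)
  attr(out, "unmatched") <- sort(nodes[cls == "core" & is.na(m)])
  out
}

#' Export an annotated network
#'
#' Writes GraphML (via igraph) and/or a SIF edge list plus a node-attribute
#' CSV, and the cluster table CSV.
#'
#' @param graph the interaction graph.
#' @param annotations node table from [annotate_effects()] (optional).
#' @param clusters result of [mcode()] (optional).
#' @param out_dir output directory, created if needed.
#' @return named vector of written file paths, invisibly.
#' @export
export_network <- function(graph, annotations = NULL, clusters = NULL,
                           out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  if (!is.null(annotations)) {
    cl_id <- rep(NA_integer_, nrow(annotations))
    if (!is.null(clusters))
      for (i in seq_along(clusters))
        cl_id[annotations$node %in% clusters[[i]]$members] <- i
    annotations$cluster_id <- cl_id
    for (col in names(annotations))
      graph <- igraph::set_vertex_attr(graph, col, value = annotations[[col]])
    p <- file.path(out_dir, "network_nodes.csv")
    utils::write.csv(annotations, p, row.names = FALSE)
    paths["nodes"] <- p
  }
  p <- file.path(out_dir, "network.graphml")
  igraph::write_graph(graph, p, format = "graphml")
  paths["graphml"] <- p
  el <- igraph::as_data_frame(graph, what = "edges")
  p <- file.path(out_dir, "network.sif")
  writeLines(paste(el$from, "pp", el$to, sep = "\t"), p)
  paths["sif"] <- p
  if (!is.null(clusters)) {
    tab <- data.frame(cluster_id = seq_along(clusters),
                      score = vapply(clusters, `[[`, 0, "score"),
                      n_nodes = vapply(clusters, `[[`, 0L, "n_nodes"),
                      n_edges = vapply(clusters, `[[`, 0L, "n_edges"),
                      seed = vapply(clusters, `[[`, "", "seed"),
                      members = vapply(clusters, function(cl)
                        paste(cl$members, collapse = ";"), ""))
    p <- file.path(out_dir, "network_clusters.csv")
    utils::write.csv(tab, p, row.names = FALSE)
    paths["clusters"] <- p
  }
  invisible(paths)
}
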