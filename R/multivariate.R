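#' Embed single cells in 2-D with t-SNE
#'
#' Channels are z-score standardized, then embedded with t-SNE (Barnes--Hut)
#' under a fixed seed so runs are reproducible. The embedding is for
#' visualization; cluster counting is done on the standardized features
#' themselves (see [select_cluster_number()]), since t-SNE distorts
#' densities.
#'
#' @param table A `feature_table` (>= 10 cells).
#' @param channels Channels to use (default: all probe channels).
#' @param perplexity t-SNE perplexity (default 30, reduced automatically
#'   when n is small).
#' @param max_iter Iterations (default 1000).
#' @param seed Integer seed (default 0).
#' @param transform Variance-stabilizing transform applied before the
#'   z-score: `"asinh"` (cytometry standard, default) or `"none"`.
#' @param cofactor arcsinh cofactor (default 5): `asinh(x / cofactor)`.
#' @return Data frame `cell_id`, `population`, `tsne1`, `tsne2`.
#' @export
embed_cells <- function(table, channels = NULL, perplexity = 30,
                        max_iter = 1000, seed = 0, transform = "asinh",
                        cofactor = 5) {
  X <- scale(stabilize_features(feature_matrix(table, channels), transform,
                                cofactor))
  n <- nrow(X)
  if (n < 10) stop("need at least 10 cells to embed")
  max_perp <- floor((n - 1) / 3)
  if (perplexity > max_perp) {
    if (max_perp < 2) stop("too few cells for any valid perplexity; ",
                           "supply more cells or duplicate-free features")
    message("perplexity reduced to ", max_perp, " for n = ", n, " cells")
    perplexity <- max_perp
  }
  set.seed(seed)
  emb <- Rtsne::Rtsne(X, dims = 2, perplexity = perplexity,
                      max_iter = max_iter, check_duplicates = FALSE,
                      pca = TRUE, verbose = FALSE)$Y
  data.frame(cell_id = table$cell_id,
             population = table$population,
             tsne1 = emb[, 1], tsne2 = emb[, 2],
             stringsAsFactors = FALSE)
}

#' Select the number of clusters by Gaussian-mixture BIC
#'
#' Fits Gaussian mixture models with k = `k_range` components on
#' variance-stabilized (arcsinh), z-score standardized features and selects
#' the k with the best BIC. The arcsinh transform is the cytometry
#' standard: intensity populations are log-normal-like, and without it a
#' Gaussian mixture splits single skewed populations. Degenerate
#' covariances fall back to diagonal models with a message.
#'
#' @param table A `feature_table` (>= 20 cells) or a numeric matrix.
#' @param channels Channels to use (default all probe channels).
#' @param k_range Candidate cluster counts (default 1:8).
#' @param seed Integer seed for the EM initialization (default 0).
#' @inheritParams embed_cells
#' @return List `k_star` (selected k), `scores` (data frame k, bic --
#'   mclust convention, larger is better), `model` (the fitted
#'   `mclust::Mclust` object), `classification` (per-cell labels).
#' @importFrom mclust Mclust mclustBIC
#' @export
select_cluster_number <- function(table, channels = NULL, k_range = 1:8,
                                  seed = 0, transform = "asinh",
                                  cofactor = 5) {
  X <- if (is.matrix(table)) table else feature_matrix(table, channels)
  if (nrow(X) < 20) stop("need at least 20 cells for cluster-number ",
                         "selection")
  X <- scale(stabilize_features(X, transform, cofactor))
  set.seed(seed)
  fit <- suppressWarnings(
    mclust::Mclust(X, G = k_range, verbose = FALSE))
  if (is.null(fit)) {
    message("full-covariance models degenerate; falling back to diagonal ",
            "covariance")
    fit <- mclust::Mclust(X, G = k_range,
                          modelNames = c("EII", "VII", "EEI", "VVI"),
                          verbose = FALSE)
  }
  bic <- apply(fit$BIC, 1, max, na.rm = TRUE)
  list(k_star = fit$G,
       scores = data.frame(k = as.integer(names(bic)), bic = as.numeric(bic)),
       model = fit, classification = fit$classification)
}

# arcsinh variance stabilization (flow/mass-cytometry convention)
stabilize_features <- function(X, transform = c("asinh", "none"),
                               cofactor = 5) {
  transform <- match.arg(transform)
  if (transform == "asinh") asinh(X / cofactor) else X
}

#' Pairwise Pearson correlation across channels, hierarchically ordered
#'
#' Correlates every pair of probe channels across cells and orders the
#' matrix by average-linkage hierarchical clustering on distance 1 - r, the
#' ordering used for correlation heatmaps.
#'
#' @param table A `feature_table` (>= 3 cells, nonzero variance per
#'   channel).
#' @param channels Channels to use (default all probe channels).
#' @return List `r` (ordered correlation matrix), `order` (channel order),
#'   `hclust` (the dendrogram object).
#' @export
correlation_matrix <- function(table, channels = NULL) {
  X <- feature_matrix(table, channels)
  if (nrow(X) < 3) stop("need at least 3 cells")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance channel(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(X)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  ord <- hc$order
  list(r = r[ord, ord], order = colnames(X)[ord], hclust = hc)
}

#' Build an inverse-correlation network over the probe channels
#'
#' A complete graph on the channels in which the target length of the edge
#' between two channels is the inverse of their correlation degree:
#' `1 / max(|r|, r_floor)` (default), or `1 - |r|`. Node positions come
#' from a stress-minimizing embedding of those target distances (Sammon
#' mapping initialized from classical MDS, both deterministic), so strongly
#' correlated channels sit close together. Centrality is the weighted
#' degree sum_j |r_ij|.
#'
#' @param r Correlation matrix (symmetric, unit diagonal), e.g.
#'   `correlation_matrix(tab)$r`, or a `feature_table` (correlations are
#'   computed first).
#' @param distance_rule `"inverse_abs"` (default) or `"one_minus_abs"`.
#' @param r_floor Floor on |r| for the inverse rule, avoiding unbounded
#'   edge lengths (default 0.05).
#' @return Object of class `correlation_network`: `nodes`, `r`,
#'   `edge_distance`, `centrality`, `layout` (2-D coordinates), `graph`
#'   (igraph object with `r` and `distance` edge attributes).
#' @export
build_network <- function(r, distance_rule = c("inverse_abs",
                                               "one_minus_abs"),
                          r_floor = 0.05) {
  distance_rule <- match.arg(distance_rule)
  if (inherits(r, "feature_table") || is.data.frame(r)) {
    r <- correlation_matrix(r)$r
  }
  stopifnot(isSymmetric(unname(r)), all(abs(r) <= 1 + 1e-8))
  nodes <- colnames(r)
  d <- switch(distance_rule,
              inverse_abs = 1 / pmax(abs(r), r_floor),
              one_minus_abs = 1 - abs(r) + r_floor)
  diag(d) <- 0
  centrality <- rowSums(abs(r)) - 1
  init <- stats::cmdscale(stats::as.dist(d), k = 2)
  layout <- tryCatch(
    MASS::sammon(stats::as.dist(d), y = jitter_dupes(init), trace = FALSE)$points,
    error = function(e) init)
  rownames(layout) <- nodes
  # adjacency from the distance matrix (strictly positive off-diagonal)
  # so the graph is complete even where r happens to be exactly 0
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$r <- r[el]
  igraph::E(g)$abs_r <- abs(r)[el]
  igraph::E(g)$distance <- d[el]
  structure(list(nodes = nodes, r = r, edge_distance = d,
                 centrality = centrality, layout = layout, graph = g,
                 distance_rule = distance_rule, r_floor = r_floor),
            class = "correlation_network")
}

# nudge exactly-duplicated MDS coordinates apart so sammon() can run
jitter_dupes <- function(y) {
  key <- paste(round(y[, 1], 9), round(y[, 2], 9))
  dup <- duplicated(key)
  if (any(dup)) {
    eps <- max(stats::dist(y)) * 1e-4 + 1e-9
    y[dup, ] <- y[dup, ] + seq_len(sum(dup)) * eps
  }
  y
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("<correlation_network> ", length(x$nodes), " nodes, ",
      igraph::ecount(x$graph), " edges (", x$distance_rule, ")\n", sep = "")
  top <- sort(x$centrality, decreasing = TRUE)[seq_len(min(3,
                                                           length(x$nodes)))]
  cat("  top centrality:", paste(sprintf("%s=%.2f", names(top), top),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Plot a correlation network
#'
#' Nodes at the stress-minimized layout, edge width proportional to |r|,
#' red for positive and blue for negative correlation.
#'
#' @param x A `correlation_network`.
#' @param min_abs_r Hide edges below this |r| for readability (default
#'   0.2; all nodes remain).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.correlation_network <- function(x, min_abs_r = 0.2, ...) {
  lay <- x$layout
  graphics::plot(lay, type = "n", xlab = "", ylab = "", axes = FALSE, ...)
  nodes <- x$nodes
  for (i in seq_along(nodes)) for (j in seq_len(i - 1)) {
    rij <- x$r[i, j]
    if (abs(rij) >= min_abs_r) {
      graphics::segments(lay[i, 1], lay[i, 2], lay[j, 1], lay[j, 2],
                         lwd = 4 * abs(rij),
                         col = if (rij > 0) "indianred" else "steelblue")
    }
  }
  sz <- 1 + 2 * x$centrality / max(x$centrality)
  graphics::points(lay, pch = 21, bg = "grey90", cex = sz)
  graphics::text(lay, labels = nodes, pos = 3, cex = 0.8, xpd = NA)
  invisible(x)
}

#' Betweenness centrality on the |r|-thresholded graph
#'
#' For module/bridge analysis: keep only edges with |r| >= `threshold`,
#' weight paths by the edge distance, and compute betweenness. Channels
#' bridging two correlation blocks attain maximal betweenness.
#'
#' @param network A `correlation_network`.
#' @param threshold |r| cutoff (default 0.3).
#' @return Named numeric vector of betweenness scores.
#' @export
network_betweenness <- function(network, threshold = 0.3) {
  g <- igraph::subgraph_from_edges(
    network$graph,
    igraph::E(network$graph)[igraph::E(network$graph)$abs_r >= threshold],
    delete.vertices = FALSE)
  igraph::betweenness(g, weights = igraph::E(g)$distance)
}

#' Compare correlation networks across treatment arms
#'
#' Builds (or accepts) one network per arm over a shared node set and
#' returns per-arm centrality tables with ranks plus each node's distance
#' to the layout centroid -- a summary of how hub-like each channel is
#' under each treatment.
#'
#' @param networks Named list of `correlation_network` objects (or of
#'   `feature_table`s, which are converted via [build_network()]).
#' @return List `centrality` (data frame: arm, node, centrality, rank
#'   where rank 1 = most central) and `layout_distance` (data frame: arm,
#'   node, distance to layout centroid).
#' @export
compare_networks <- function(networks) {
  networks <- lapply(networks, function(nw) {
    if (inherits(nw, "correlation_network")) nw else build_network(nw)
  })
  node_sets <- lapply(networks, `[[`, "nodes")
  if (!all(vapply(node_sets, setequal, logical(1), node_sets[[1]]))) {
    stop("all arms must share the same node set")
  }
  arms <- names(networks) %||% paste0("arm", seq_along(networks))
  centr <- do.call(rbind, lapply(seq_along(networks), function(i) {
    ce <- networks[[i]]$centrality
    data.frame(arm = arms[i], node = names(ce), centrality = ce,
               rank = rank(-ce, ties.method = "min"),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  layd <- do.call(rbind, lapply(seq_along(networks), function(i) {
    lay <- networks[[i]]$layout
    ctr <- colMeans(lay)
    data.frame(arm = arms[i], node = rownames(lay),
               distance = sqrt(rowSums(sweep(lay, 2, ctr)^2)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(centrality = centr, layout_distance = layd)
}

#' Export a network as an edge-list CSV and GraphML
#'
#' @param network A `correlation_network`.
#' @param csv_path Edge-list CSV path (`node_i, node_j, r, distance`), or
#'   `NULL` to skip.
#' @param graphml_path GraphML path, or `NULL` to skip.
#' @return Invisibly, the edge-list data frame.
#' @export
write_network <- function(network, csv_path = NULL, graphml_path = NULL) {
  nodes <- network$nodes
  lt <- which(lower.tri(network$r), arr.ind = TRUE)
  edges <- data.frame(node_i = nodes[lt[, 2]], node_j = nodes[lt[, 1]],
                      r = network$r[lt],
                      distance = network$edge_distance[lt],
                      stringsAsFactors = FALSE)
  if (!is.null(csv_path)) utils::write.csv(edges, csv_path,
                                           row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  }
  invisible(edges)
}
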