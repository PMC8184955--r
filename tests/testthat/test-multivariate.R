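test_that("duplicated cells embed at near-identical positions", {
  out <- fx_features(preset_surface(n_cells = 40), seed = 51)
  ft <- out$features
  dup <- rbind(ft, ft)
  dup$cell_id <- c(ft$cell_id, paste0(ft$cell_id, "_copy"))
  class(dup) <- class(ft)
  attr(dup, "channels") <- feature_channels(ft)
  emb <- embed_cells(dup, seed = 0)
  n <- nrow(ft)
  pair_d <- sqrt((emb$tsne1[1:n] - emb$tsne1[n + 1:n])^2 +
                 (emb$tsne2[1:n] - emb$tsne2[n + 1:n])^2)
  all_d <- stats::dist(cbind(emb$tsne1[1:n], emb$tsne2[1:n]))
  expect_lt(median(pair_d), 0.2 * median(all_d))
})

test_that("separated populations embed with high silhouette, homogeneous ones do not", {
  skip_if_not_installed("cluster")
  out <- fx_features(preset_endocytosis(n_cells = 100), seed = 52)
  ft <- out$features
  emb <- embed_cells(ft, channels = c("Endo40", "Endo70", "Endo120"),
                     seed = 0)
  lab <- as.integer(factor(emb$population))
  sil <- cluster::silhouette(lab, stats::dist(cbind(emb$tsne1, emb$tsne2)))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  # one homogeneous population: an arbitrary bipartition scores near zero
  one <- fx_features(preset_surface(n_cells = 100), seed = 53)
  ft1 <- one$features[one$features$population == "HeLa", ]
  class(ft1) <- class(one$features)
  attr(ft1, "channels") <- feature_channels(one$features)
  emb1 <- embed_cells(ft1, channels = c("CD44", "CD55"), seed = 0)
  xy <- cbind(emb1$tsne1, emb1$tsne2)
  split <- rep(1:2, length.out = nrow(xy))
  sil1 <- cluster::silhouette(split, stats::dist(xy))
  expect_lt(mean(sil1[, "sil_width"]), 0.25)
  expect_error(embed_cells(ft[1:5, ]), "at least 10 cells")
})

test_that("GMM-BIC selects the designed number of populations", {
  endo <- fx_features(preset_endocytosis(n_cells = 100), seed = 54)
  sel3 <- select_cluster_number(endo$features,
                                channels = c("Endo40", "Endo70",
                                             "Endo120"), seed = 0)
  expect_equal(sel3$k_star, 3)
  surf <- fx_features(preset_surface(n_cells = 100), seed = 55)
  sel2 <- select_cluster_number(surf$features,
                                channels = c("CD44", "CD55"), seed = 0)
  expect_equal(sel2$k_star, 2)
  # a single homogeneous population selects k = 1
  ft1 <- surf$features[surf$features$population == "HeLa", ]
  class(ft1) <- class(surf$features)
  attr(ft1, "channels") <- feature_channels(surf$features)
  sel1 <- select_cluster_number(ft1, channels = c("CD44", "CD55"),
                                seed = 0)
  expect_equal(sel1$k_star, 1)
  expect_equal(sel3$scores$k, 1:8)
})

test_that("correlation matrices are symmetric with planted structure recovered", {
  out <- fx_features(preset_drugs(n_cells = 60), seed = 56)
  cm <- correlation_matrix(out$features)
  expect_equal(diag(cm$r), setNames(rep(1, 14), rownames(cm$r)))
  expect_equal(cm$r, t(cm$r))
  expect_true(all(abs(cm$r) <= 1 + 1e-12))

  # planted latent factor between two channels: r = 0.8 in log space
  R <- diag(2)
  R[1, 2] <- R[2, 1] <- 0.8
  dimnames(R) <- list(c("MUC1", "EpCAM"), c("MUC1", "EpCAM"))
  pop <- population_spec("A", 500, c(MUC1 = 90, EpCAM = 110), cv = 0.35,
                         latent_cor = R)
  tr <- sample_abundances(pop, fx_panel, seed = 57)
  r_hat <- cor(tr$MUC1, tr$EpCAM)
  expect_gt(r_hat, 0.7)
  expect_lt(r_hat, 0.9)

  # independent channels: off-diagonal correlations stay near zero
  pop0 <- population_spec("A", 500,
                          stats::setNames(rep(50, 14),
                                          panel_components(fx_panel,
                                                           role = "probe")),
                          cv = 0.35, common_rho = 0)
  tr0 <- sample_abundances(pop0, fx_panel, seed = 58)
  r0 <- cor(as.matrix(tr0[, panel_components(fx_panel, role = "probe")]))
  diag(r0) <- 0
  expect_lt(max(abs(r0)), 0.15)

  const <- out$features
  const$HER2 <- 1
  expect_error(correlation_matrix(const), "HER2")
})

test_that("network edges, distances and centrality follow the correlations", {
  out <- fx_features(preset_drugs(n_cells = 60), seed = 59)
  nw <- build_network(correlation_matrix(out$features)$r)
  expect_equal(igraph::ecount(nw$graph), 14 * 13 / 2)  # complete graph
  expect_equal(nw$edge_distance, t(nw$edge_distance))
  # distance decreases in |r|: the strongest pair has the shortest edge
  off <- abs(nw$r)
  diag(off) <- NA
  d_off <- nw$edge_distance
  diag(d_off) <- NA
  expect_equal(which.max(off), which.min(d_off))
  # |r| = 1 pair attains the global minimum distance
  r2 <- diag(3)
  r2[1, 2] <- r2[2, 1] <- 1
  r2[1, 3] <- r2[3, 1] <- 0.2
  r2[2, 3] <- r2[3, 2] <- 0.1
  dimnames(r2) <- list(letters[1:3], letters[1:3])
  nw2 <- build_network(r2)
  expect_equal(nw2$edge_distance["a", "b"],
               min(nw2$edge_distance[upper.tri(nw2$edge_distance)]))
})

test_that("a planted hub channel attains the top weighted-degree centrality", {
  probes <- panel_components(fx_panel, role = "probe")
  R <- diag(14)
  dimnames(R) <- list(probes, probes)
  hub <- "EpCAM"
  spokes <- setdiff(probes, hub)[1:8]
  R[hub, spokes] <- R[spokes, hub] <- 0.6
  pop <- population_spec("A", 400,
                         stats::setNames(rep(60, 14), probes), cv = 0.35,
                         latent_cor = R)
  tr <- sample_abundances(pop, fx_panel, seed = 60)
  r_hat <- cor(as.matrix(tr[, probes]))
  nw <- build_network(r_hat)
  expect_equal(names(which.max(nw$centrality)), hub)
})

test_that("layout distances decrease with |r| (planted structure)", {
  probes <- panel_components(fx_panel, role = "probe")
  # graded single-factor structure: loadings 0.15..0.95 give pairwise
  # correlations spanning two orders of magnitude
  lam <- seq(0.15, 0.95, length.out = 14)
  R <- outer(lam, lam)
  diag(R) <- 1
  dimnames(R) <- list(probes, probes)
  pop <- population_spec("A", 500,
                         stats::setNames(rep(60, 14), probes), cv = 0.35,
                         latent_cor = R)
  tr <- sample_abundances(pop, fx_panel, seed = 61)
  nw <- build_network(cor(as.matrix(tr[, probes])))
  lay_d <- as.matrix(stats::dist(nw$layout))
  ut <- upper.tri(lay_d)
  rho <- stats::cor(lay_d[ut], abs(nw$r)[ut], method = "spearman")
  expect_lt(rho, -0.8)
})

test_that("bridge channels between correlation blocks maximize betweenness", {
  probes <- panel_components(fx_panel, role = "probe")
  R <- diag(14)
  dimnames(R) <- list(probes, probes)
  b1 <- probes[1:6]; b2 <- probes[7:12]; bridge <- probes[13:14]
  R[b1, b1] <- 0.6; R[b2, b2] <- 0.6
  R[bridge, b1] <- R[bridge, b2] <- 0.45
  R[b1, bridge] <- R[b2, bridge] <- 0.45
  R[bridge, bridge] <- 0.6
  diag(R) <- 1
  pop <- population_spec("A", 500,
                         stats::setNames(rep(60, 14), probes), cv = 0.35,
                         latent_cor = R)
  tr <- sample_abundances(pop, fx_panel, seed = 62)
  nw <- build_network(cor(as.matrix(tr[, probes])))
  btw <- network_betweenness(nw, threshold = 0.3)
  expect_true(names(which.max(btw)) %in% bridge)
})

test_that("network comparison ranks arms consistently", {
  out <- fx_features(preset_drugs(n_cells = 50), seed = 63)
  ft <- out$features
  nw <- build_network(correlation_matrix(ft)$r)
  cmp <- compare_networks(list(ctrl = nw, same = nw))
  ce <- cmp$centrality
  expect_identical(ce$rank[ce$arm == "ctrl"], ce$rank[ce$arm == "same"])
  # node-set mismatch is rejected
  r_small <- correlation_matrix(ft,
                                channels = feature_channels(ft)[1:5])$r
  expect_error(compare_networks(list(a = nw,
                                     b = build_network(r_small))),
               "node set")
})

test_that("network export produces a parseable edge list and GraphML", {
  out <- fx_features(preset_drugs(n_cells = 40), seed = 64)
  nw <- build_network(correlation_matrix(out$features)$r)
  csv <- withr::local_tempfile(fileext = ".csv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  edges <- write_network(nw, csv, gml)
  expect_equal(nrow(edges), 91)
  back <- read.csv(csv)
  expect_equal(names(back), c("node_i", "node_j", "r", "distance"))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 14)
})
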