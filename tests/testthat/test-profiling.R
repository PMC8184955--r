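test_that("feature tables have 14 probe columns with auxiliaries aside", {
  out <- fx_features(preset_surface(n_cells = 40), seed = 41)
  ft <- out$features
  expect_s3_class(ft, "feature_table")
  expect_length(feature_channels(ft), 14)
  expect_equal(nrow(ft), out$qc$n_retained)
  expect_named(attr(ft, "aux"), c("Amide12C", "PS"))
  # empty input keeps the header intact
  empty <- build_feature_table(list(), fx_panel)
  expect_equal(nrow(empty), 0)
  expect_length(feature_channels(empty), 14)
})

test_that("mixed-panel results are rejected", {
  out <- fx_features(preset_surface(n_cells = 40), seed = 41)
  sp <- fx_clean_spectrum()
  other_panel <- panel_config(Filter(function(co) co$name != "HER2",
                                     fx_panel$components))
  other_lib <- build_library(other_panel, verbose = FALSE)
  u_other <- unmix_cell(sp, library = other_lib)
  sq <- fx_sim_qc(preset_surface(n_cells = 40), seed = 41)
  res <- unmix_set(sq$qc$retained, fx_lib)
  expect_error(build_feature_table(c(res, list(u_other)), fx_panel),
               "panel")
})

test_that("control normalization returns 1 for the control arm", {
  out <- fx_features(preset_inhibitors(n_cells = 60), seed = 42)
  nrm <- normalize_to_control(out$features, "Control")
  expect_equal(unname(nrm$population_means["Control", ]),
               rep(1, 14), tolerance = 1e-12)
  expect_error(normalize_to_control(out$features, "NoSuchArm"),
               "not present")
})

test_that("designed fold changes are recovered in normalized means", {
  design <- list(
    population_spec("Control", 200, c(Endo40 = 100, Endo70 = 80,
                                      Amide12C = 250)),
    population_spec("Doubled", 200, fold_change = c(Endo40 = 2.0)),
    population_spec("Same", 200, fold_change = c(Endo40 = 1.0)))
  sim <- simulate_experiment(design, fx_panel,
                             noise_spec(outlier_fraction = 0), seed = 43,
                             control = "Control", library = fx_lib)
  res <- unmix_set(remove_background(sim$spectra)$spectra, fx_lib)
  ft <- build_feature_table(res, fx_panel,
                            labels = sim$truth[, c("cell_id",
                                                   "population")])
  nrm <- normalize_to_control(ft, "Control")
  expect_equal(unname(nrm$population_means["Doubled", "Endo40"]), 2.0,
               tolerance = 0.15)
  expect_equal(unname(nrm$population_means["Same", "Endo40"]), 1.0,
               tolerance = 0.1)
})

test_that("normalization is invariant to global intensity rescaling", {
  out <- fx_features(preset_inhibitors(n_cells = 40), seed = 44)
  ft <- out$features
  scaled <- ft
  ch <- feature_channels(ft)
  scaled[ch] <- scaled[ch] * 7.3
  n1 <- normalize_to_control(ft, "Control")
  n2 <- normalize_to_control(scaled, "Control")
  expect_equal(n1$population_means, n2$population_means, tolerance = 1e-12)
})

test_that("fold-change radar reproduces the inhibitor patterns", {
  out <- fx_features(preset_inhibitors(n_cells = 150), seed = 45)
  ft <- out$features
  endo <- c("Endo40", "Endo70", "Endo120")
  # control versus itself: all fold changes exactly 1
  expect_equal(unname(fold_change_radar(ft, "Control", "Control", endo)),
               rep(1, 3))
  # clathrin inhibitor suppresses uptake of all sizes
  expect_true(all(fold_change_radar(ft, "CPZ", "Control", endo) < 1))
  # caveolae inhibitor spares 40 nm, suppresses 70/120 nm
  nys <- fold_change_radar(ft, "Nystatin", "Control", endo)
  expect_gte(nys[["Endo40"]], 1)
  expect_lt(nys[["Endo70"]], 1)
  expect_lt(nys[["Endo120"]], 1)
  expect_error(fold_change_radar(ft, "CPZ", "Control", "NoChannel"),
               "NoChannel")
})

test_that("box statistics use the half-IQR whisker convention", {
  out <- fx_features(preset_surface(n_cells = 50), seed = 46)
  gs <- group_stats(out$features, "CD44", c("HeLa", "SKBR3"))
  st <- gs$stats
  x <- out$features$CD44[out$features$population == "HeLa"]
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- diff(q)
  expect_equal(st$lo_whisker[1], min(x[x >= q[1] - 0.5 * iqr]))
  expect_equal(st$hi_whisker[1], max(x[x <= q[2] + 0.5 * iqr]))
  # whiskers never extend beyond the data
  expect_gte(st$lo_whisker[1], min(x))
  expect_lte(st$hi_whisker[1], max(x))
  # identical values collapse the box onto the median
  const <- out$features
  const$CD44 <- 5
  gs0 <- group_stats(const, "CD44", c("HeLa", "SKBR3"))
  expect_equal(gs0$stats$q1, gs0$stats$q3)
  expect_equal(gs0$stats$lo_whisker, gs0$stats$median)
  expect_error(group_stats(out$features, "CD44", c("HeLa", "Missing")),
               "Missing")
})

test_that("the two-group test has correct type-I behavior and power", {
  # same distribution: p > 0.05 in at least 90% of replicate seeds
  p_null <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rlnorm(200, log(50), 0.3)
    y <- rlnorm(200, log(50), 0.3)
    stats::wilcox.test(x, y, exact = FALSE)$p.value
  }, numeric(1))
  expect_gte(mean(p_null > 0.05), 0.9)
  # 2x mean shift at cv 0.3, n = 200: decisive
  design <- list(population_spec("lo", 200, c(CD44 = 50), cv = 0.3),
                 population_spec("hi", 200, c(CD44 = 100), cv = 0.3))
  sim <- simulate_experiment(design, fx_panel,
                             noise_spec(outlier_fraction = 0), seed = 47,
                             library = fx_lib)
  res <- unmix_set(remove_background(sim$spectra)$spectra, fx_lib)
  ft <- build_feature_table(res, fx_panel,
                            labels = sim$truth[, c("cell_id",
                                                   "population")])
  gs <- group_stats(ft, "CD44", c("lo", "hi"))
  expect_lt(gs$p_value, 0.001)
})

test_that("feature tables export with auxiliary channels", {
  out <- fx_features(preset_surface(n_cells = 40), seed = 48)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(out$features, path)
  df <- read.csv(path, check.names = FALSE)
  expect_true(all(c("cell_id", "population", "fidelity_r", "CD44",
                    "aux_Amide12C", "aux_PS") %in% names(df)))
  expect_equal(nrow(df), nrow(out$features))
})
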