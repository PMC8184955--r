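test_that("default panel has 14 probes + 2 auxiliaries split 3/13 by window", {
  expect_length(fx_panel$components, 16)
  expect_length(panel_components(fx_panel, role = "probe"), 14)
  expect_length(panel_components(fx_panel, role = "auxiliary"), 2)
  expect_equal(ncol(fx_lib$M_amide), 3)
  expect_equal(ncol(fx_lib$M_silent), 13)
  expect_equal(ncol(fx_lib$M_amide) + ncol(fx_lib$M_silent), 16)
  # removing one silent probe drops the silent column count to 12
  smaller <- panel_config(Filter(function(co) co$name != "HER2",
                                 fx_panel$components))
  lib2 <- build_library(smaller, verbose = FALSE)
  expect_equal(ncol(lib2$M_silent), 12)
})

test_that("rendered components are unit-max and peak where specified", {
  grid <- seq(2000, 2300)
  y <- render_component(fx_panel$components$Nucleolin, grid)
  expect_equal(grid[which.max(y)], 2218)
  for (nm in c("HER2", "CD44", "AltQ2")) {
    prof <- render_component(fx_panel$components[[nm]], grid)
    expect_equal(max(prof), 1.0)
    expect_equal(grid[which.max(prof)],
                 fx_panel$components[[nm]]$peaks$center)
  }
  # every library column is unit-max normalized
  expect_equal(unname(apply(fx_lib$M_amide, 2, max)), rep(1, 3))
  expect_equal(unname(apply(fx_lib$M_silent, 2, max)), rep(1, 13))
})

test_that("amide components sit at 1574/1659 with a 40 cm^-1 13C downshift", {
  c12 <- sort(fx_panel$components$Amide12C$peaks$center)
  c13 <- sort(fx_panel$components$Amide13C$peaks$center)
  expect_equal(c12, c(1574, 1659))
  expect_equal(c12 - c13, c(40, 40))
})

test_that("two-peak rendering is symmetric under swapping peak parameters", {
  grid <- seq(1500, 1700, by = 0.5)
  a <- reference_component("a", "amide",
                           data.frame(center = c(1550, 1650),
                                      fwhm = c(12, 18),
                                      amplitude = c(1, 1)))
  b <- reference_component("b", "amide",
                           data.frame(center = c(1650, 1550),
                                      fwhm = c(18, 12),
                                      amplitude = c(1, 1)))
  expect_equal(render_component(a, grid), render_component(b, grid))
})

test_that("resolvability report finds the minimum Rdot peak separation", {
  rdots <- c(2052, 2079, 2092, 2118, 2133, 2153, 2175, 2194, 2207, 2218)
  d <- abs(outer(rdots, rdots, "-"))
  diag(d) <- Inf
  expect_equal(min(d), 11)  # 2218 - 2207
  rdot_comps <- lapply(seq_along(rdots), function(i) {
    reference_component(paste0("R", rdots[i]), "silent",
                        data.frame(center = rdots[i], fwhm = 15,
                                   amplitude = 1))
  })
  rep_rdot <- check_resolvability(
    build_library(panel_config(c(rdot_comps, list(
      reference_component("amide", "amide",
                          data.frame(center = 1600, fwhm = 15,
                                     amplitude = 1), "auxiliary")))),
      verbose = FALSE))
  expect_equal(rep_rdot$silent$min_center_separation, 11)
  expect_setequal(rep_rdot$silent$closest_pair, c("R2207", "R2218"))
  # identical duplicated components give column correlation 1 and an
  # error from the library rank check
  dup <- panel_config(list(
    reference_component("x1", "silent",
                        data.frame(center = 2100, fwhm = 15, amplitude = 1)),
    reference_component("x2", "silent",
                        data.frame(center = 2100.4, fwhm = 15,
                                   amplitude = 1)),
    reference_component("am", "amide",
                        data.frame(center = 1600, fwhm = 15, amplitude = 1),
                        "auxiliary")), grid_step = 1)
  libd <- build_library(dup, verbose = FALSE)
  expect_gt(check_resolvability(libd)$silent$max_column_correlation, 0.999)
  # widely spaced narrow peaks are nearly uncorrelated
  far <- panel_config(list(
    reference_component("lo", "silent",
                        data.frame(center = 2020, fwhm = 5, amplitude = 1)),
    reference_component("hi", "silent",
                        data.frame(center = 2280, fwhm = 5, amplitude = 1)),
    reference_component("am", "amide",
                        data.frame(center = 1600, fwhm = 15, amplitude = 1),
                        "auxiliary")))
  libf <- build_library(far, verbose = FALSE)
  expect_lt(abs(check_resolvability(libf)$silent$max_column_correlation),
            0.06)
})

test_that("window column counts always sum to the panel size", {
  set.seed(101)
  for (rep in 1:5) {
    n_am <- sample(1:3, 1)
    n_si <- sample(2:8, 1)
    comps <- c(
      lapply(seq_len(n_am), function(i) {
        reference_component(paste0("a", i), "amide",
                            data.frame(center = 1500 + 60 * i, fwhm = 15,
                                       amplitude = 1))
      }),
      lapply(seq_len(n_si), function(i) {
        reference_component(paste0("s", i), "silent",
                            data.frame(center = 2000 + 35 * i, fwhm = 15,
                                       amplitude = 1))
      }))
    lib <- build_library(panel_config(comps), verbose = FALSE)
    expect_equal(ncol(lib$M_amide) + ncol(lib$M_silent), n_am + n_si)
  }
})

test_that("argmax wavenumber is stable under doubling grid resolution", {
  for (nm in c("Nucleolin", "Amide12C", "EdU")) {
    co <- fx_panel$components[[nm]]
    w <- raman_windows()[[co$window]]
    g1 <- seq(w[1], w[2], by = 1)
    g2 <- seq(w[1], w[2], by = 0.5)
    y1 <- render_component(co, g1)
    y2 <- render_component(co, g2)
    expect_equal(g1[which.max(y1)], g2[which.max(y2)])
  }
})

test_that("invalid components and out-of-grid renders are rejected", {
  expect_error(reference_component("bad", "silent",
                                   data.frame(center = 1600, fwhm = 15,
                                              amplitude = 1)),
               "outside the silent window")
  expect_error(reference_component("bad", "amide",
                                   data.frame(center = 1600, fwhm = -1,
                                              amplitude = 1)),
               "positive")
  expect_error(render_component(fx_panel$components$Nucleolin,
                                seq(1500, 1700)),
               "Nucleolin")
})

test_that("panel YAML round-trips and library exports as wide CSV", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_panel_yaml(fx_panel, path)
  p2 <- read_panel_yaml(path)
  expect_equal(names(p2$components), names(fx_panel$components))
  expect_equal(p2$components$Amide13C$peaks, fx_panel$components$
                 Amide13C$peaks)
  lib2 <- build_library(p2, verbose = FALSE)
  expect_equal(lib2$M_silent, fx_lib$M_silent)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_library_csv(fx_lib, csv)
  df <- read.csv(csv, check.names = FALSE)
  expect_equal(names(df)[1], "wavenumber")
  expect_equal(ncol(df), 17)  # wavenumber + 16 components
  expect_equal(nrow(df), 201 + 301)
})

test_that("the shipped default panel file reproduces the default library", {
  path <- system.file("extdata", "panel_default.yaml",
                      package = "ramanplex")
  expect_true(nzchar(path))
  p <- read_panel_yaml(path)
  lib <- build_library(p, verbose = FALSE)
  expect_equal(lib$M_amide, fx_lib$M_amide)
  expect_equal(lib$M_silent, fx_lib$M_silent)
})
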