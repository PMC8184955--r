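#' Analysis windows of the probe panel
#'
#' The two wavenumber windows used throughout: the protein amide region
#' (1500--1700 cm^-1, amide I/II backbone bands) and the cell-silent region
#' (2000--2300 cm^-1), where endogenous cellular species have no Raman bands
#' and narrow-band probes can be read out background-free.
#'
#' @return Named list with numeric `c(lo, hi)` bounds (cm^-1) per window.
#' @export
raman_windows <- function() {
  list(amide = c(1500, 1700), silent = c(2000, 2300))
}

#' Define a reference spectral component
#'
#' A component is a named, parametrically rendered reference spectrum: one or
#' more peaks (center, FWHM, relative amplitude) assigned to one analysis
#' window. Components with `role = "probe"` become feature-table channels;
#' `role = "auxiliary"` components (the endogenous 12C amide envelope and the
#' polystyrene C=C band of the nanoparticle carrier) are needed for unmixing
#' but are not reported as probe channels.
#'
#' @param name Component identifier (unique within a panel).
#' @param window `"amide"` or `"silent"`.
#' @param peaks Data frame (or coercible) with columns `center`, `fwhm`,
#'   `amplitude`; centers in cm^-1, FWHM in cm^-1, amplitudes unitless
#'   (relative; the rendered profile is rescaled to unit maximum).
#' @param role `"probe"` or `"auxiliary"`.
#' @return An object of class `reference_component`.
#' @export
reference_component <- function(name, window, peaks, role = "probe") {
  window <- match.arg(window, c("amide", "silent"))
  role <- match.arg(role, c("probe", "auxiliary"))
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("center", "fwhm", "amplitude") %in% names(peaks)))
  peaks <- peaks[, c("center", "fwhm", "amplitude")]
  if (nrow(peaks) < 1L) {
    stop("component '", name, "': at least one peak is required")
  }
  if (any(peaks$fwhm <= 0) || any(peaks$amplitude <= 0)) {
    stop("component '", name, "': fwhm and amplitude must be positive")
  }
  win <- raman_windows()[[window]]
  bad <- peaks$center < win[1] | peaks$center > win[2]
  if (any(bad)) {
    stop("component '", name, "': peak center(s) ",
         paste(peaks$center[bad], collapse = ", "),
         " outside the ", window, " window [", win[1], ", ", win[2], "] cm^-1")
  }
  structure(list(name = name, window = window, peaks = peaks, role = role),
            class = "reference_component")
}

#' @export
print.reference_component <- function(x, ...) {
  cat("<reference_component> ", x$name, " (", x$role, ", ", x$window,
      " window)\n", sep = "")
  print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' The default 16-component panel
#'
#' Fourteen probe components plus two auxiliaries:
#' \itemize{
#'   \item Seven surface-protein probes, Raman-dot (Rdot) conjugates against
#'     HER2 (2052), CD44 (2079), EGFR (2133), CD55 (2153), MUC1 (2175),
#'     EpCAM (2194) and nucleolin (2218 cm^-1).
#'   \item Three endocytic probes, Rdots of 40 nm (2207), 70 nm (2118) and
#'     120 nm (2092 cm^-1) diameter whose uptake reports size-dependent
#'     endocytosis.
#'   \item Four metabolic probes: 13C-amide (new protein synthesis via
#'     13C-amino-acid labeling; amide II/I at 1534/1619 cm^-1, i.e. the
#'     endogenous 1574/1659 bands downshifted by 40 cm^-1), 13C-EdU (DNA
#'     synthesis), 17-ODYA (fatty-acid metabolism) and the alkyne-tagged CoQ
#'     analog AltQ2 (mitochondrial electron transport).
#'   \item Two auxiliaries: the endogenous 12C amide envelope (1574 and
#'     1659 cm^-1, amide I : amide II amplitude 1.5 : 1) and the polystyrene
#'     C=C band of the Rdot carrier beads.
#' }
#'
#' Silent-window centers of the metabolic probes (13C-EdU, 17-ODYA, AltQ2)
#' and the PS C=C center are configurable placeholders chosen for mutual
#' resolvability (2065, 2250, 2290 and 1602 cm^-1); override them via
#' `centers` when calibrated values are available.
#'
#' @param fwhm Default peak FWHM in cm^-1 applied to every peak (default 15).
#' @param centers Optional named numeric vector overriding single-peak
#'   component centers, e.g. `c(AltQ2 = 2285)`.
#' @return A `panel_config` object (see [panel_config()]).
#' @export
default_panel <- function(fwhm = 15, centers = NULL) {
  single <- c(
    # surface-protein Rdot conjugates
    HER2 = 2052, CD44 = 2079, EGFR = 2133, CD55 = 2153,
    MUC1 = 2175, EpCAM = 2194, Nucleolin = 2218,
    # endocytic Rdots by particle diameter
    Endo40 = 2207, Endo70 = 2118, Endo120 = 2092,
    # metabolic probes (placeholder centers, configurable)
    EdU = 2065, ODYA = 2250, AltQ2 = 2290,
    # auxiliary: polystyrene C=C of the Rdot carrier (placeholder center)
    PS = 1602
  )
  if (!is.null(centers)) {
    unknown <- setdiff(names(centers), names(single))
    if (length(unknown)) stop("unknown component(s): ",
                              paste(unknown, collapse = ", "))
    single[names(centers)] <- centers
  }
  pk <- function(center, amp = 1) {
    data.frame(center = center, fwhm = fwhm, amplitude = amp)
  }
  comps <- lapply(names(single), function(nm) {
    window <- if (single[[nm]] < 1700) "amide" else "silent"
    role <- if (nm == "PS") "auxiliary" else "probe"
    reference_component(nm, window, pk(single[[nm]]), role)
  })
  # amide I : amide II = 1.5 : 1; 13C labeling downshifts both bands 40 cm^-1
  comps <- c(comps, list(
    reference_component("Amide13C", "amide",
                        data.frame(center = c(1534, 1619), fwhm = fwhm,
                                   amplitude = c(1, 1.5)), "probe"),
    reference_component("Amide12C", "amide",
                        data.frame(center = c(1574, 1659), fwhm = fwhm,
                                   amplitude = c(1, 1.5)), "auxiliary")
  ))
  panel_config(comps)
}

#' Assemble a panel configuration
#'
#' Validates the component set and fixes grids and component order. Order is
#' alphabetical within each window unless `component_order` overrides it, so
#' that unmixed weight indices are stable across runs.
#'
#' @param components List of [reference_component()] objects.
#' @param grid_step Wavenumber grid step in cm^-1 (default 1).
#' @param component_order Optional character vector giving the full ordering.
#' @return Object of class `panel_config` with elements `components`
#'   (named list), `grid_amide`, `grid_silent`, `grid_step`.
#' @export
panel_config <- function(components, grid_step = 1, component_order = NULL) {
  stopifnot(length(components) > 0,
            all(vapply(components, inherits, logical(1),
                       "reference_component")))
  nms <- vapply(components, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate component names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  if (!is.null(component_order)) {
    if (!setequal(component_order, nms)) {
      stop("component_order must be a permutation of the component names")
    }
    ord <- match(component_order, nms)
  } else {
    win <- vapply(components, `[[`, character(1), "window")
    # radix = C-locale collation, identical on every platform/locale
    ord <- order(match(win, c("amide", "silent")), nms, method = "radix")
  }
  components <- components[ord]
  names(components) <- vapply(components, `[[`, character(1), "name")
  sil <- Filter(function(co) co$window == "silent", components)
  sil_centers <- unlist(lapply(sil, function(co) co$peaks$center))
  if (anyDuplicated(sil_centers)) {
    stop("silent-window peak centers must be mutually distinct; duplicated: ",
         paste(unique(sil_centers[duplicated(sil_centers)]), collapse = ", "))
  }
  w <- raman_windows()
  structure(list(
    components = components,
    grid_amide = seq(w$amide[1], w$amide[2], by = grid_step),
    grid_silent = seq(w$silent[1], w$silent[2], by = grid_step),
    grid_step = grid_step
  ), class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  role <- vapply(x$components, `[[`, character(1), "role")
  win <- vapply(x$components, `[[`, character(1), "window")
  cat("<panel_config> ", length(x$components), " components (",
      sum(role == "probe"), " probes, ", sum(role == "auxiliary"),
      " auxiliary); grid step ", x$grid_step, " cm^-1\n", sep = "")
  for (w in c("amide", "silent")) {
    cat(" ", w, ": ", paste(names(x$components)[win == w], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Names of panel components by role/window
#'
#' @param panel A `panel_config`.
#' @param role Optional role filter (`"probe"` / `"auxiliary"`).
#' @param window Optional window filter.
#' @return Character vector of component names in panel order.
#' @export
panel_components <- function(panel, role = NULL, window = NULL) {
  keep <- rep(TRUE, length(panel$components))
  if (!is.null(role)) {
    keep <- keep & vapply(panel$components, `[[`, character(1), "role") == role
  }
  if (!is.null(window)) {
    keep <- keep &
      vapply(panel$components, `[[`, character(1), "window") == window
  }
  names(panel$components)[keep]
}

# Lorentzian / Gaussian / pseudo-Voigt lineshapes, unit height at the center.
lineshape_fun <- function(lineshape = c("lorentzian", "gaussian",
                                        "pseudo-voigt"), eta = 0.5) {
  lineshape <- match.arg(lineshape)
  lor <- function(x, center, fwhm) {
    hw2 <- (fwhm / 2)^2
    hw2 / ((x - center)^2 + hw2)
  }
  gau <- function(x, center, fwhm) {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    exp(-(x - center)^2 / (2 * s^2))
  }
  switch(lineshape,
         lorentzian = lor,
         gaussian = gau,
         `pseudo-voigt` = function(x, center, fwhm) {
           eta * lor(x, center, fwhm) + (1 - eta) * gau(x, center, fwhm)
         })
}

#' Render a reference component on a wavenumber grid
#'
#' Evaluates the sum of the component's peak lineshapes on `grid` and
#' rescales to unit maximum, the normalization convention of the reference
#' library.
#'
#' @param component A [reference_component()].
#' @param grid Ascending wavenumber grid (cm^-1).
#' @param lineshape `"lorentzian"` (default, the standard condensed-phase
#'   Raman lineshape), `"gaussian"`, or `"pseudo-voigt"`.
#' @param eta Lorentzian fraction for the pseudo-Voigt profile.
#' @return Numeric intensity vector on `grid`, max = 1.
#' @export
render_component <- function(component, grid,
                             lineshape = c("lorentzian", "gaussian",
                                           "pseudo-voigt"), eta = 0.5) {
  stopifnot(inherits(component, "reference_component"))
  if (any(component$peaks$center < min(grid) |
          component$peaks$center > max(grid))) {
    stop("component '", component$name, "' (", component$window,
         " window): peak center outside the supplied grid [",
         min(grid), ", ", max(grid), "] cm^-1")
  }
  f <- lineshape_fun(lineshape, eta)
  y <- rep(0, length(grid))
  for (i in seq_len(nrow(component$peaks))) {
    p <- component$peaks[i, ]
    y <- y + p$amplitude * f(grid, p$center, p$fwhm)
  }
  y / max(y)
}

#' Build the two-window reference library
#'
#' Renders every panel component on its window's grid and assembles the two
#' library matrices M_amide and M_silent whose columns (unit-max normalized)
#' are the reference spectra used for linear unmixing.
#'
#' @param panel A [panel_config()].
#' @inheritParams render_component
#' @param verbose Report condition numbers of both matrices (default TRUE).
#' @return Object of class `raman_library`: matrices `M_amide`, `M_silent`
#'   (rows = grid points, named columns), `grid_amide`, `grid_silent`,
#'   `component_order` (per window), `condition` (per-window condition
#'   numbers), `panel`.
#' @export
build_library <- function(panel, lineshape = "lorentzian", eta = 0.5,
                          verbose = TRUE) {
  stopifnot(inherits(panel, "panel_config"))
  render_window <- function(window) {
    grid <- panel[[paste0("grid_", window)]]
    nms <- panel_components(panel, window = window)
    M <- vapply(nms, function(nm) {
      render_component(panel$components[[nm]], grid, lineshape, eta)
    }, numeric(length(grid)))
    rownames(M) <- grid
    M
  }
  M_amide <- render_window("amide")
  M_silent <- render_window("silent")
  for (w in list(list("M_amide", M_amide), list("M_silent", M_silent))) {
    M <- w[[2]]
    r <- qr(M)$rank
    if (r < ncol(M)) {
      cc <- stats::cor(M)
      diag(cc) <- 0
      worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
      stop(w[[1]], " is rank deficient at this grid resolution (rank ", r,
           " < ", ncol(M), "); most collinear columns: ",
           colnames(M)[worst[1]], ", ", colnames(M)[worst[2]])
    }
  }
  cond <- c(amide = kappa(M_amide, exact = TRUE),
            silent = kappa(M_silent, exact = TRUE))
  if (verbose) {
    message(sprintf(
      "reference library: %d amide + %d silent columns; condition numbers %.3g (amide), %.3g (silent)",
      ncol(M_amide), ncol(M_silent), cond["amide"], cond["silent"]))
  }
  structure(list(
    M_amide = M_amide, M_silent = M_silent,
    grid_amide = panel$grid_amide, grid_silent = panel$grid_silent,
    component_order = list(amide = colnames(M_amide),
                           silent = colnames(M_silent)),
    condition = cond, panel = panel
  ), class = "raman_library")
}

#' @export
print.raman_library <- function(x, ...) {
  cat("<raman_library> M_amide ", nrow(x$M_amide), "x", ncol(x$M_amide),
      ", M_silent ", nrow(x$M_silent), "x", ncol(x$M_silent),
      sprintf("; condition %.3g / %.3g\n", x$condition["amide"],
              x$condition["silent"]), sep = "")
  invisible(x)
}

#' Resolvability report for a reference library
#'
#' For each window, reports the minimum pairwise separation between primary
#' peak centers and the maximum off-diagonal Pearson correlation between
#' library columns -- the two quantities that determine whether the panel's
#' components can be mutually separated by unmixing.
#'
#' @param library A [build_library()] result.
#' @return List per window: `min_center_separation` (cm^-1),
#'   `max_column_correlation`, and the corresponding pairs.
#' @export
check_resolvability <- function(library) {
  stopifnot(inherits(library, "raman_library"))
  one <- function(M, window) {
    comps <- library$panel$components[colnames(M)]
    centers <- vapply(comps, function(co) {
      co$peaks$center[which.max(co$peaks$amplitude)]
    }, numeric(1))
    if (length(centers) > 1) {
      d <- abs(outer(centers, centers, "-"))
      diag(d) <- Inf
      ij <- which(d == min(d), arr.ind = TRUE)[1, ]
      min_sep <- min(d)
      sep_pair <- colnames(M)[ij]
      cc <- stats::cor(M)
      diag(cc) <- -Inf
      ij2 <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      max_cor <- max(cc)
      cor_pair <- colnames(M)[ij2]
    } else {
      min_sep <- Inf; sep_pair <- character(0)
      max_cor <- NA_real_; cor_pair <- character(0)
    }
    list(window = window, min_center_separation = min_sep,
         closest_pair = sep_pair, max_column_correlation = max_cor,
         most_correlated_pair = cor_pair)
  }
  list(amide = one(library$M_amide, "amide"),
       silent = one(library$M_silent, "silent"))
}

#' Write / read a panel configuration as YAML
#'
#' The document is a list of components with keys `name`, `window`, `role`
#' and `peaks` (each peak: `center`, `fwhm`, `amplitude`), plus a top-level
#' `grid_step`. The default panel ships in
#' `system.file("extdata", "panel_default.yaml", package = "ramanplex")`.
#'
#' @param panel A `panel_config`.
#' @param path File path.
#' @return `read_panel_yaml` returns a `panel_config`; `write_panel_yaml`
#'   returns `path` invisibly.
#' @export
write_panel_yaml <- function(panel, path) {
  stopifnot(inherits(panel, "panel_config"))
  doc <- list(
    grid_step = panel$grid_step,
    components = lapply(unname(panel$components), function(co) {
      list(name = co$name, window = co$window, role = co$role,
           peaks = lapply(seq_len(nrow(co$peaks)), function(i) {
             as.list(co$peaks[i, ])
           }))
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_panel_yaml
#' @export
read_panel_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  comps <- lapply(doc$components, function(co) {
    peaks <- do.call(rbind, lapply(co$peaks, as.data.frame))
    reference_component(co$name, co$window, peaks, co$role)
  })
  panel_config(comps, grid_step = doc$grid_step %||% 1)
}

#' Export a reference library as a wide CSV
#'
#' First column `wavenumber` (cm^-1), one column per component. Both windows
#' are stacked row-wise (amide rows first).
#'
#' @param library A `raman_library`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_library_csv <- function(library, path) {
  pad <- function(M, all_cols) {
    out <- matrix(0, nrow(M), length(all_cols),
                  dimnames = list(NULL, all_cols))
    out[, colnames(M)] <- M
    out
  }
  cols <- c(colnames(library$M_amide), colnames(library$M_silent))
  df <- data.frame(
    wavenumber = c(library$grid_amide, library$grid_silent),
    rbind(pad(library$M_amide, cols), pad(library$M_silent, cols)),
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
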