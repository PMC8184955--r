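#' Specify a simulated cell population
#'
#' A population (cell line or treatment arm) is described by per-component
#' mean abundances (arbitrary intensity units -- the reference spectra are
#' unit-max, so an abundance is directly a peak height), a coefficient of
#' variation describing cell-to-cell spread, and optional fold changes
#' relative to a control arm. Components not mentioned get mean 0.
#'
#' @param name Population label.
#' @param n_cells Number of cells (>= 1).
#' @param mean_abundance Named non-negative numeric vector of per-component
#'   means; may be `NULL` for treatment arms that inherit the control arm's
#'   means via `fold_change`.
#' @param cv Coefficient of variation, scalar or named per-component
#'   (>= 0; default 0.35).
#' @param fold_change Named positive multipliers applied to the (inherited
#'   or own) means; unlisted components get 1.
#' @param latent_cor Optional correlation matrix (named dims) imposed on the
#'   log-abundances, used to plant correlation structure across channels;
#'   overrides `common_rho`.
#' @param common_rho Default correlation between every pair of channels'
#'   log-abundances (default 0.9), emulating the shared cell-to-cell
#'   factor (cell size, staining and uptake capacity) that dominates
#'   intensity spread in cytometry data and makes multiparameter
#'   intensities predominantly positively correlated. With the default cv
#'   of 0.35 this leaves a residual per-channel (spectral-shape) cv of
#'   about 0.11, so intact cells stay mutually consistent while total
#'   spread remains wide; set 0 for fully independent channels.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(name, n_cells, mean_abundance = NULL, cv = 0.35,
                            fold_change = NULL, latent_cor = NULL,
                            common_rho = 0.9) {
  stopifnot(n_cells >= 1, all(cv >= 0))
  if (!is.null(mean_abundance)) {
    stopifnot(!is.null(names(mean_abundance)), all(mean_abundance >= 0))
  }
  if (!is.null(fold_change)) {
    stopifnot(!is.null(names(fold_change)), all(fold_change > 0))
  }
  if (!is.null(latent_cor)) {
    stopifnot(isSymmetric(unname(latent_cor)),
              !is.null(rownames(latent_cor)))
  }
  stopifnot(common_rho >= 0, common_rho < 1)
  structure(list(name = name, n_cells = as.integer(n_cells),
                 mean_abundance = mean_abundance, cv = cv,
                 fold_change = fold_change, latent_cor = latent_cor,
                 common_rho = common_rho),
            class = "population_spec")
}

#' Specify measurement noise, baseline and outliers
#'
#' Describes everything in a simulated spectrum that is not probe signal:
#' additive per-point Gaussian noise (the noise term of the linear mixing
#' model), a smooth baseline, and the fraction of corrupted (outlier)
#' acquisitions such as debris or mis-parked cells.
#'
#' @param additive_sigma Gaussian noise s.d. per grid point (intensity
#'   units; default 2).
#' @param baseline_amplitude Peak amplitude of the smooth baseline (default
#'   20).
#' @param baseline_shape `"polynomial"` (low-order, per-cell random
#'   coefficients) or `"broad-gaussian"`.
#' @param outlier_fraction Probability that a cell's spectrum is corrupted
#'   (in \[0, 0.5); default 0.02).
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(additive_sigma = 2, baseline_amplitude = 20,
                       baseline_shape = c("polynomial", "broad-gaussian"),
                       outlier_fraction = 0.02) {
  baseline_shape <- match.arg(baseline_shape)
  stopifnot(additive_sigma >= 0, baseline_amplitude >= 0,
            outlier_fraction >= 0, outlier_fraction < 0.5)
  structure(list(additive_sigma = additive_sigma,
                 baseline_amplitude = baseline_amplitude,
                 baseline_shape = baseline_shape,
                 outlier_fraction = outlier_fraction),
            class = "noise_spec")
}

# log-normal draws with exact specified mean and cv; cv = 0 degenerates to
# the mean. z is an optional pre-drawn standard-normal matrix (for planting
# correlation in log space).
rlnorm_mean_cv <- function(n, mean, cv, z = NULL) {
  if (mean <= 0) return(rep(0, n))
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  if (is.null(z)) z <- stats::rnorm(n)
  exp(meanlog + sdlog * z)
}

#' Draw per-cell ground-truth abundances for one population
#'
#' Abundances are log-normal (positive, right-skewed, the standard model for
#' cytometry-like intensity spread) with the population's mean x fold_change
#' and CV per component. With `latent_cor` set, log-abundances are drawn
#' jointly normal with that correlation, planting cross-channel structure.
#'
#' @param pop A [population_spec()].
#' @param panel A [panel_config()]; defines component order.
#' @param seed Optional integer seed (draws are deterministic given it).
#' @param control_mean Named means of the control arm, used when `pop`
#'   carries fold changes but no means of its own.
#' @return Data frame: `cell_id`, `population`, `is_outlier` (all `FALSE`;
#'   flags are assigned by [simulate_experiment()]), then one abundance
#'   column per panel component in panel order.
#' @export
sample_abundances <- function(pop, panel, seed = NULL, control_mean = NULL) {
  stopifnot(inherits(pop, "population_spec"), inherits(panel, "panel_config"))
  if (!is.null(seed)) set.seed(seed)
  comps <- names(panel$components)
  base <- stats::setNames(rep(0, length(comps)), comps)
  src <- pop$mean_abundance %||% control_mean
  if (is.null(src)) stop("population '", pop$name,
                         "' has no mean_abundance and no control to inherit")
  unknown <- setdiff(names(src), comps)
  if (length(unknown)) stop("unknown component(s) in mean_abundance of '",
                            pop$name, "': ", paste(unknown, collapse = ", "))
  base[names(src)] <- src
  if (!is.null(pop$fold_change)) {
    unknown <- setdiff(names(pop$fold_change), comps)
    if (length(unknown)) stop("unknown component(s) in fold_change of '",
                              pop$name, "': ",
                              paste(unknown, collapse = ", "))
    base[names(pop$fold_change)] <- base[names(pop$fold_change)] *
      pop$fold_change
  }
  cv <- if (length(pop$cv) == 1) stats::setNames(rep(pop$cv, length(comps)),
                                                 comps) else {
    out <- stats::setNames(rep(0.35, length(comps)), comps)
    out[names(pop$cv)] <- pop$cv
    out
  }
  n <- pop$n_cells
  Z <- NULL
  R <- diag(length(comps))
  dimnames(R) <- list(comps, comps)
  if (!is.null(pop$latent_cor)) {
    sub <- intersect(rownames(pop$latent_cor), comps)
    R[sub, sub] <- pop$latent_cor[sub, sub]
  } else if (pop$common_rho > 0) {
    R[] <- pop$common_rho
    diag(R) <- 1
  }
  if (any(R[lower.tri(R)] != 0)) {
    # repair an indefinite requested correlation (e.g. a planted hub too
    # strong to be jointly consistent) by eigenvalue clipping
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) < 1e-8) {
      R <- stats::cov2cor(ev$vectors %*% diag(pmax(ev$values, 1e-8)) %*%
                            t(ev$vectors))
      dimnames(R) <- list(comps, comps)
    }
    Z <- matrix(stats::rnorm(n * length(comps)), n) %*% chol(R)
    colnames(Z) <- comps
  }
  theta <- vapply(comps, function(nm) {
    rlnorm_mean_cv(n, base[[nm]], cv[[nm]],
                   z = if (is.null(Z)) NULL else Z[, nm])
  }, numeric(n))
  theta <- matrix(theta, nrow = n, dimnames = list(NULL, comps))
  data.frame(cell_id = sprintf("%s_%04d", pop$name, seq_len(n)),
             population = pop$name, is_outlier = FALSE, theta,
             check.names = FALSE, stringsAsFactors = FALSE)
}

# smooth per-cell baseline on [0,1]-scaled coordinate, unit max amplitude
random_baseline <- function(x, shape) {
  t <- (x - min(x)) / diff(range(x))
  b <- switch(shape,
    polynomial = {
      co <- stats::rnorm(4)
      co[1] + co[2] * t + co[3] * t^2 + co[4] * t^3
    },
    `broad-gaussian` = {
      centers <- stats::runif(2)
      widths <- stats::runif(2, 0.3, 0.6)
      amps <- stats::runif(2, 0.5, 1)
      amps[1] * exp(-(t - centers[1])^2 / (2 * widths[1]^2)) +
        amps[2] * exp(-(t - centers[2])^2 / (2 * widths[2]^2))
    })
  b <- b - min(b)
  if (max(b) > 0) b <- b / max(b)
  b
}

#' Render one cell's whole-cell Raman spectrum
#'
#' The generative counterpart of unmixing: within each analysis window the
#' signal is exactly library-matrix times abundance vector; the gap between
#' windows carries baseline/noise only. A smooth baseline and additive
#' Gaussian noise are added; outlier cells are replaced by a random smooth
#' curve (plus noise) emulating debris or a mis-parked acquisition, which
#' guarantees low correlation with the population's peaked mean spectrum.
#'
#' @param theta Named non-negative abundance vector covering all library
#'   components (one row of [sample_abundances()] output works).
#' @param library A [build_library()] result.
#' @param noise A [noise_spec()].
#' @param is_outlier Corrupt this spectrum?
#' @param seed Optional integer seed.
#' @return List `wavenumber`, `intensity` (full 1500--2300 cm^-1 grid).
#' @export
render_cell_spectrum <- function(theta, library, noise = noise_spec(),
                                 is_outlier = FALSE, seed = NULL) {
  stopifnot(inherits(library, "raman_library"))
  if (!is.null(seed)) set.seed(seed)
  theta <- unlist(theta)
  all_comp <- c(library$component_order$amide, library$component_order$silent)
  missing <- setdiff(all_comp, names(theta))
  if (length(missing)) stop("theta is missing component(s): ",
                            paste(missing, collapse = ", "))
  step <- diff(library$grid_amide[1:2])
  wn <- seq(min(library$grid_amide), max(library$grid_silent), by = step)
  y <- rep(0, length(wn))
  ia <- match(library$grid_amide, wn)
  is <- match(library$grid_silent, wn)
  y[ia] <- library$M_amide %*% theta[library$component_order$amide]
  y[is] <- library$M_silent %*% theta[library$component_order$silent]
  if (is_outlier) {
    # magnitude comparable to a real cell, morphology smooth and peak-free
    scale <- max(max(y), 1) * stats::runif(1, 0.5, 2)
    y <- scale * random_baseline(wn, "broad-gaussian")
  }
  if (noise$baseline_amplitude > 0) {
    y <- y + noise$baseline_amplitude *
      random_baseline(wn, noise$baseline_shape)
  }
  if (noise$additive_sigma > 0) {
    y <- y + stats::rnorm(length(wn), 0, noise$additive_sigma)
  }
  list(wavenumber = wn, intensity = y)
}

#' Simulate a multi-arm single-cell Raman experiment
#'
#' Draws ground-truth abundances per population, flags outlier cells, and
#' renders every spectrum, standing in for the automated whole-cell Raman
#' acquisition. All randomness flows from `seed`; identical seeds give
#' identical output.
#'
#' @param design List of [population_spec()]s with distinct names.
#' @param panel A [panel_config()] (default [default_panel()]).
#' @param noise A [noise_spec()].
#' @param seed Integer seed (default 1).
#' @param control Name of the control arm; required when any arm inherits
#'   means or applies fold changes.
#' @param library Optional pre-built [build_library()] (rebuilt otherwise).
#' @return List with `spectra` (a [spectrum_set()] with population labels)
#'   and `truth` (data frame of per-cell ground-truth abundances and
#'   outlier flags).
#' @export
simulate_experiment <- function(design, panel = default_panel(),
                                noise = noise_spec(), seed = 1,
                                control = NULL, library = NULL) {
  if (inherits(design, "population_spec")) design <- list(design)
  nms <- vapply(design, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate population names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  needs_control <- vapply(design, function(p) {
    is.null(p$mean_abundance) || !is.null(p$fold_change)
  }, logical(1))
  control_mean <- NULL
  if (!is.null(control)) {
    if (!control %in% nms) stop("control arm '", control, "' not in design")
    control_mean <- design[[match(control, nms)]]$mean_abundance
  } else if (any(needs_control)) {
    stop("fold changes or inherited means require a named control arm")
  }
  if (is.null(library)) library <- build_library(panel, verbose = FALSE)
  set.seed(seed)
  truth <- do.call(rbind, lapply(design, sample_abundances, panel = panel,
                                 control_mean = control_mean))
  truth$is_outlier <- stats::runif(nrow(truth)) < noise$outlier_fraction
  comps <- names(panel$components)
  spectra <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    spectra[[i]] <- render_cell_spectrum(
      unlist(truth[i, comps]), library, noise,
      is_outlier = truth$is_outlier[i])
  }
  intensity <- vapply(spectra, `[[`, numeric(length(spectra[[1]]$wavenumber)),
                      "intensity")
  set <- spectrum_set(spectra[[1]]$wavenumber, intensity,
                      cell_id = truth$cell_id,
                      meta = truth[, c("cell_id", "population")])
  list(spectra = set, truth = truth)
}

#' Shipped experiment presets
#'
#' Ready-made [simulate_experiment()] designs mirroring the structure (not
#' the magnitudes) of the profiling experiments the pipeline targets. All
#' abundance means and fold changes are plausible placeholder values, not
#' measured quantities.
#'
#' \describe{
#'   \item{`preset_surface()`}{Two cell lines measured on two surface
#'     channels, with HeLa expressing markedly more CD44 and CD55 than
#'     SKBR3 -- two clearly separable populations.}
#'   \item{`preset_endocytosis()`}{Three cell lines (HeLa, SKBR3, COS-7)
#'     with distinct uptake profiles of 40/70/120 nm endocytic probes --
#'     three populations separable only by combining the three channels.}
#'   \item{`preset_inhibitors()`}{Endocytosis inhibitor panel: CPZ
#'     (clathrin) suppresses uptake of all sizes; nystatin (caveolae)
#'     spares 40 nm but suppresses 70/120 nm; 4 degC blocks all; short
#'     cytochalasin D suppresses and long exposure enhances uptake.}
#'   \item{`preset_drugs()`}{Six-arm chemotherapy panel over all 14 probe
#'     channels (control, cytochalasin D, cycloheximide, trastuzumab,
#'     cisplatin, H2O2), each drug moving its mechanistic channels:
#'     e.g. cycloheximide suppresses 13C-amide (protein synthesis),
#'     cisplatin suppresses EdU (DNA synthesis), trastuzumab lowers
#'     HER2.}
#' }
#'
#' @param n_cells Cells per arm.
#' @param cv Coefficient of variation of each channel.
#' @return List with elements `design` (list of [population_spec()]),
#'   `control` (arm name) and `channels` (the informative channels).
#' @export
preset_surface <- function(n_cells = 150, cv = 0.35) {
  list(design = list(
    population_spec("HeLa", n_cells,
                    c(CD44 = 120, CD55 = 90, Amide12C = 250, PS = 25),
                    cv = cv),
    population_spec("SKBR3", n_cells,
                    c(CD44 = 25, CD55 = 20, Amide12C = 250, PS = 8),
                    cv = cv)),
    control = NULL, channels = c("CD44", "CD55"))
}

#' @rdname preset_surface
#' @export
preset_endocytosis <- function(n_cells = 150, cv = 0.35) {
  aux <- c(Amide12C = 250)
  list(design = list(
    population_spec("HeLa", n_cells,
                    c(Endo40 = 100, Endo70 = 80, Endo120 = 60, PS = 30, aux),
                    cv = cv),
    population_spec("SKBR3", n_cells,
                    c(Endo40 = 25, Endo70 = 95, Endo120 = 85, PS = 26, aux),
                    cv = cv),
    population_spec("COS7", n_cells,
                    c(Endo40 = 55, Endo70 = 22, Endo120 = 110, PS = 24, aux),
                    cv = cv)),
    control = NULL, channels = c("Endo40", "Endo70", "Endo120"))
}

#' @rdname preset_surface
#' @export
preset_inhibitors <- function(n_cells = 150, cv = 0.35) {
  ctrl <- c(Endo40 = 100, Endo70 = 80, Endo120 = 60,
            PS = 30, Amide12C = 250)
  arm <- function(name, f40, f70, f120) {
    population_spec(name, n_cells, cv = cv,
                    fold_change = c(Endo40 = f40, Endo70 = f70,
                                    Endo120 = f120))
  }
  list(design = list(
    population_spec("Control", n_cells, ctrl, cv = cv),
    arm("CPZ", 0.45, 0.50, 0.40),
    arm("Nystatin", 1.10, 0.55, 0.40),
    arm("Cold4C", 0.25, 0.25, 0.20),
    arm("CytoD_6h", 0.55, 0.60, 0.50),
    arm("CytoD_60h", 1.60, 1.80, 1.70)),
    control = "Control", channels = c("Endo40", "Endo70", "Endo120"))
}

#' @rdname preset_surface
#' @export
preset_drugs <- function(n_cells = 150, cv = 0.35) {
  ctrl <- c(HER2 = 150, CD44 = 40, EGFR = 70, CD55 = 60, MUC1 = 90,
            EpCAM = 110, Nucleolin = 80,
            Endo40 = 70, Endo70 = 55, Endo120 = 45,
            EdU = 35, ODYA = 50, AltQ2 = 40, Amide13C = 120,
            Amide12C = 250, PS = 35)
  arm <- function(name, fold) population_spec(name, n_cells, cv = cv,
                                              fold_change = fold)
  list(design = list(
    population_spec("Control", n_cells, ctrl, cv = cv),
    arm("CytoD", c(Endo40 = 0.55, Endo70 = 0.60, Endo120 = 0.50,
                   PS = 0.6)),
    arm("CHX", c(Amide13C = 0.30, EdU = 0.80, ODYA = 0.85)),
    arm("Trastuzumab", c(HER2 = 0.50, EdU = 0.80)),
    arm("Cisplatin", c(EdU = 0.30, Amide13C = 0.80, Nucleolin = 0.85)),
    arm("H2O2", c(AltQ2 = 0.55, ODYA = 0.75, EdU = 0.70, Amide13C = 0.80))),
    control = "Control",
    channels = setdiff(names(ctrl), c("Amide12C", "PS")))
}

#' Write / read ground-truth abundance tables
#'
#' Plain CSV keyed by `cell_id`, round-trippable without loss (up to float
#' formatting).
#'
#' @param truth Truth data frame from [simulate_experiment()].
#' @param path CSV path.
#' @return `read_truth_csv` returns the data frame; `write_truth_csv`
#'   returns `path` invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
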