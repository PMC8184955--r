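#' Trim a spectrum (set) to the two analysis windows
#'
#' Extracts the amide (1500--1700 cm^-1) and cell-silent (2000--2300 cm^-1)
#' segments, inclusive bounds, grid preserved. Unmixing operates on these
#' two segments independently.
#'
#' @param wavenumber Ascending grid (cm^-1), or a [spectrum_set()] in which
#'   case `intensity` is taken from it.
#' @param intensity Intensity vector or matrix (rows = grid points).
#' @return List with `amide` and `silent`, each a list `wavenumber`,
#'   `intensity`.
#' @export
trim_windows <- function(wavenumber, intensity = NULL) {
  if (inherits(wavenumber, "spectrum_set")) {
    intensity <- wavenumber$intensity
    wavenumber <- wavenumber$wavenumber
  }
  w <- raman_windows()
  out <- lapply(names(w), function(nm) {
    rng <- w[[nm]]
    if (min(wavenumber) > rng[1] || max(wavenumber) < rng[2]) {
      stop("spectrum grid [", min(wavenumber), ", ", max(wavenumber),
           "] does not cover the ", nm, " window [", rng[1], ", ", rng[2],
           "] cm^-1")
    }
    keep <- wavenumber >= rng[1] & wavenumber <= rng[2]
    if (is.matrix(intensity)) {
      list(wavenumber = wavenumber[keep],
           intensity = intensity[keep, , drop = FALSE])
    } else {
      list(wavenumber = wavenumber[keep], intensity = intensity[keep])
    }
  })
  names(out) <- names(w)
  out
}

# Asymmetric least squares baseline (Eilers-style): iteratively reweighted
# penalized smoother in which points above the current baseline (peaks) get
# weight p << 1 and points below get 1 - p.
als_baseline <- function(y, lambda = 1e6, p = 0.01, maxit = 10) {
  n <- length(y)
  if (n < 4) return(rep(min(y), n))
  P <- als_penalty(n, lambda)
  w <- rep(1, n)
  z <- y
  chol_sym <- NULL
  for (it in seq_len(maxit)) {
    A <- P + Matrix::Diagonal(n, w)
    # pentadiagonal pattern is constant: reuse the symbolic factorization
    chol_sym <- if (is.null(chol_sym)) {
      Matrix::Cholesky(A, LDL = FALSE)
    } else {
      Matrix::update(chol_sym, A)
    }
    z <- as.numeric(Matrix::solve(chol_sym, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  z
}

# cache the (n, lambda)-dependent smoothness penalty across cells
als_env <- new.env(parent = emptyenv())
als_penalty <- function(n, lambda) {
  key <- paste0(n, "_", lambda)
  if (is.null(als_env[[key]])) {
    D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                            diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                             rep(1, n - 2)))
    als_env[[key]] <- lambda * Matrix::crossprod(D)
  }
  als_env[[key]]
}

# Iterative polynomial baseline: refit excluding points far above the fit,
# keeping at least min_frac of the points so the fit cannot collapse.
poly_baseline <- function(x, y, degree = 3, maxit = 30, k = 1,
                          min_frac = 0.15) {
  t <- (x - mean(x)) / stats::sd(x)
  B <- cbind(1, stats::poly(t, degree, raw = TRUE))
  n <- length(y)
  floor_n <- max(degree + 2, ceiling(min_frac * n))
  keep <- rep(TRUE, n)
  z <- y
  for (it in seq_len(maxit)) {
    co <- stats::lm.fit(B[keep, , drop = FALSE], y[keep])$coefficients
    co[is.na(co)] <- 0
    z <- as.numeric(B %*% co)
    resid <- y - z
    s <- stats::sd(resid[keep])
    if (!is.finite(s) || s == 0) break
    keep_new <- resid < k * s
    if (sum(keep_new) < floor_n) {
      keep_new <- resid <= sort(resid)[floor_n]
    }
    if (all(keep_new == keep)) break
    keep <- keep_new
  }
  z
}

#' Remove the smooth background from a spectrum
#'
#' Estimates a smooth baseline and subtracts it, returning both the
#' corrected spectrum and the baseline estimate for inspection. Linear in
#' the input: `remove(c * I) = c * remove(I)` for both methods.
#'
#' @param wavenumber Grid (cm^-1), or a [spectrum_set()] (then applied
#'   column-wise and a corrected `spectrum_set` is returned).
#' @param intensity Intensity vector (ignored for a set).
#' @param method `"polynomial"` -- iterative low-order polynomial fit that
#'   excludes peak points and refits until convergence (default; on
#'   peak-crowded panels the lower envelope never returns to baseline
#'   between peaks, which biases envelope-tracking methods, while peak
#'   exclusion anchored in the peak-free 1700--2000 cm^-1 gap stays
#'   unbiased); `"als"` -- asymmetric least squares, an iteratively
#'   reweighted penalized smoother tracking the lower envelope.
#' @param lambda ALS smoothness penalty (default 1e6).
#' @param p ALS asymmetry: weight of points above the baseline (default
#'   0.01).
#' @param degree Polynomial degree for `method = "polynomial"` (default 3).
#' @return For a vector: list `corrected`, `baseline`, `wavenumber`. For a
#'   `spectrum_set`: list `spectra` (corrected set), `baseline` (matrix).
#' @export
remove_background <- function(wavenumber, intensity = NULL,
                              method = c("polynomial", "als"),
                              lambda = 1e6, p = 0.01, degree = 3) {
  if (is.character(method) && !all(method %in% c("als", "polynomial"))) {
    stop("unknown background method '", method[1],
         "'; available: als, polynomial")
  }
  method <- match.arg(method)
  if (inherits(wavenumber, "spectrum_set")) {
    set <- wavenumber
    base <- apply(set$intensity, 2, function(y) {
      if (method == "als") als_baseline(y, lambda, p)
      else poly_baseline(set$wavenumber, y, degree)
    })
    corrected <- set$intensity - base
    return(list(spectra = spectrum_set(set$wavenumber, corrected,
                                       set$cell_id, set$meta),
                baseline = base))
  }
  y <- intensity
  z <- if (method == "als") als_baseline(y, lambda, p)
       else poly_baseline(wavenumber, y, degree)
  list(corrected = y - z, baseline = z, wavenumber = wavenumber)
}

#' Exclude outlier cells by the Pearson-correlation rule
#'
#' Each cell's spectrum is correlated against a reference built from the
#' other cells of its group; cells with r strictly below `threshold`
#' (default 0.95) are excluded, emulating the acquisition-QC rule that
#' spectra poorly correlated with the rest of their sample are debris or
#' failed acquisitions. The correlation is computed on the concatenated
#' analysis windows; pass background-corrected spectra for best behavior.
#'
#' @param spectra A [spectrum_set()]; groups taken from
#'   `spectra$meta$population` when present (else one group).
#' @param threshold Exclusion threshold (strict `<`; default 0.95).
#' @param reference `"loo-mean"` -- mean spectrum of the group excluding
#'   the cell itself (default) -- or `"pairwise-median"` -- median pairwise
#'   correlation with the other cells.
#' @param trim Compute correlations on the concatenated amide + silent
#'   windows (default TRUE; requires the grid to cover both).
#' @return List `retained` (a `spectrum_set`) and `report` (class
#'   `qc_report`): per-cell correlation, excluded flag, threshold, counts.
#' @export
filter_outliers <- function(spectra, threshold = 0.95,
                            reference = c("loo-mean", "pairwise-median"),
                            trim = TRUE) {
  stopifnot(inherits(spectra, "spectrum_set"))
  reference <- match.arg(reference)
  groups <- spectra$meta$population %||% rep("all", length(spectra))
  if (any(table(groups) < 3)) {
    stop("each sample group needs >= 3 spectra for the group reference ",
         "to be defined")
  }
  X <- if (trim) {
    tw <- trim_windows(spectra)
    rbind(tw$amide$intensity, tw$silent$intensity)
  } else spectra$intensity
  r <- numeric(length(spectra))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    Xg <- X[, idx, drop = FALSE]
    if (reference == "loo-mean") {
      tot <- rowSums(Xg)
      for (j in seq_along(idx)) {
        ref <- (tot - Xg[, j]) / (length(idx) - 1)
        r[idx[j]] <- stats::cor(Xg[, j], ref)
      }
    } else {
      cc <- stats::cor(Xg)
      diag(cc) <- NA
      r[idx] <- apply(cc, 2, stats::median, na.rm = TRUE)
    }
  }
  excluded <- r < threshold
  report <- structure(list(
    n_input = length(spectra), n_excluded = sum(excluded),
    n_retained = sum(!excluded),
    excluded_ids = spectra$cell_id[excluded],
    threshold = threshold, reference = reference,
    table = data.frame(cell_id = spectra$cell_id, group = groups,
                       correlation = r, excluded = excluded,
                       stringsAsFactors = FALSE)
  ), class = "qc_report")
  list(retained = spectra[!excluded], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$n_input, " cells in, ", x$n_excluded,
      " excluded (r < ", x$threshold, ", reference = ", x$reference, ")\n",
      sep = "")
  if (x$n_excluded > 0) {
    cat("  excluded:", paste(x$excluded_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a QC report as CSV (per cell) plus a JSON summary
#'
#' @param report A `qc_report` from [filter_outliers()].
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_qc_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "qc_report"))
  if (!is.null(csv_path)) {
    utils::write.csv(report$table, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_input = report$n_input, n_excluded = report$n_excluded,
           n_retained = report$n_retained, threshold = report$threshold,
           reference = report$reference, excluded_ids = report$excluded_ids),
      json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(report)
}
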