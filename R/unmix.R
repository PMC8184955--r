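#' Linearly unmix one window against a reference library matrix
#'
#' Solves the per-window linear mixing model I = M theta + N for the
#' component weights. The library matrix is tall (grid points x components),
#' so the matrix inverse of the square case generalizes to least squares:
#' `mode = "ls"` minimizes ||I - M theta||_2 via QR; `mode = "nnls"` adds
#' the physical constraint theta >= 0 (Lawson--Hanson NNLS).
#'
#' @param I Intensity vector (one window) or matrix with one column per
#'   cell.
#' @param M Library matrix for the window, full column rank.
#' @param mode `"nnls"` (default) or `"ls"`.
#' @return For a vector `I`: list `theta` (named weights), `residual`
#'   (I - M theta). For a matrix: list `theta` (components x cells),
#'   `residual` (matrix).
#' @export
unmix_window <- function(I, M, mode = c("nnls", "ls")) {
  mode <- match.arg(mode)
  M <- as.matrix(M)
  vec <- !is.matrix(I)
  Imat <- if (vec) matrix(I, ncol = 1) else as.matrix(I)
  if (nrow(Imat) != nrow(M)) {
    stop("dimension mismatch: length(I) = ", nrow(Imat), " but M has ",
         nrow(M), " rows")
  }
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    stop("library matrix is rank deficient (rank ", qrM$rank, " < ",
         ncol(M), " columns); components are not separable on this grid")
  }
  theta <- if (mode == "ls") {
    qr.coef(qrM, Imat)
  } else {
    apply(Imat, 2, function(y) pracma::lsqnonneg(M, y)$x)
  }
  theta <- matrix(theta, nrow = ncol(M),
                  dimnames = list(colnames(M), colnames(Imat)))
  residual <- Imat - M %*% theta
  if (vec) {
    list(theta = stats::setNames(theta[, 1], colnames(M)),
         residual = residual[, 1])
  } else {
    list(theta = theta, residual = residual)
  }
}

#' Pearson reconstruction fidelity
#'
#' The per-cell QC metric of the unmixing model: the Pearson product-moment
#' correlation between a measured spectrum and its library-times-weights
#' reconstruction.
#'
#' @param original,reconstruction Equal-length numeric vectors with nonzero
#'   variance.
#' @return Pearson r in \[-1, 1\].
#' @export
reconstruction_fidelity <- function(original, reconstruction) {
  if (length(original) != length(reconstruction)) {
    stop("vectors must have equal length")
  }
  if (stats::sd(original) == 0 || stats::sd(reconstruction) == 0) {
    stop("reconstruction fidelity undefined for zero-variance input")
  }
  stats::cor(original, reconstruction)
}

#' Unmix a single cell spectrum over both analysis windows
#'
#' Trims the spectrum to the amide and silent windows (optionally removing
#' background first), unmixes each window independently against the
#' library, assembles the reconstruction, and scores fidelity as the
#' Pearson correlation between the input and the reconstruction over the
#' concatenated windows.
#'
#' @param wavenumber Full grid (cm^-1), or a list with `wavenumber` /
#'   `intensity` as returned by [render_cell_spectrum()].
#' @param intensity Intensity vector (ignored if `wavenumber` is a list).
#' @param library A [build_library()] result.
#' @param mode `"nnls"` (default) or `"ls"`.
#' @param remove_bg Apply [remove_background()] per window first (default
#'   FALSE; the pipeline removes background once, up front).
#' @param cell_id Optional identifier carried into the result.
#' @return Object of class `unmix_result`: `theta_amide`, `theta_silent`
#'   (named weights), per-window `residual`, `reconstruction` (list with
#'   per-window grids and values), `fidelity_r`, `cell_id`, `mode`.
#' @export
unmix_cell <- function(wavenumber, intensity = NULL, library,
                       mode = c("nnls", "ls"), remove_bg = FALSE,
                       cell_id = NULL) {
  mode <- match.arg(mode)
  if (is.list(wavenumber) && !is.null(wavenumber$intensity)) {
    intensity <- wavenumber$intensity
    wavenumber <- wavenumber$wavenumber
  }
  tw <- trim_windows(wavenumber, intensity)
  if (!identical(as.numeric(tw$amide$wavenumber),
                 as.numeric(library$grid_amide)) ||
      !identical(as.numeric(tw$silent$wavenumber),
                 as.numeric(library$grid_silent))) {
    stop("spectrum grid does not match the library grid within the windows")
  }
  ya <- tw$amide$intensity
  ys <- tw$silent$intensity
  if (remove_bg) {
    ya <- remove_background(tw$amide$wavenumber, ya)$corrected
    ys <- remove_background(tw$silent$wavenumber, ys)$corrected
  }
  ua <- unmix_window(ya, library$M_amide, mode)
  us <- unmix_window(ys, library$M_silent, mode)
  recon_a <- as.numeric(library$M_amide %*% ua$theta)
  recon_s <- as.numeric(library$M_silent %*% us$theta)
  structure(list(
    cell_id = cell_id,
    theta_amide = ua$theta, theta_silent = us$theta,
    residual = list(amide = ua$residual, silent = us$residual),
    reconstruction = list(amide = recon_a, silent = recon_s,
                          grid_amide = library$grid_amide,
                          grid_silent = library$grid_silent),
    fidelity_r = reconstruction_fidelity(c(ya, ys), c(recon_a, recon_s)),
    mode = mode
  ), class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  cat("<unmix_result>", if (!is.null(x$cell_id)) x$cell_id else "",
      sprintf(" mode=%s fidelity_r=%.4f\n", x$mode, x$fidelity_r))
  print(round(c(x$theta_amide, x$theta_silent), 3))
  invisible(x)
}

#' Unmix every cell of a spectrum set
#'
#' Batch version of [unmix_cell()]. In least-squares mode the whole set is
#' solved in one QR factorization per window; NNLS solves per cell.
#'
#' @param spectra A [spectrum_set()] (grid must cover both windows and
#'   match the library grid within them).
#' @param library A [build_library()] result.
#' @inheritParams unmix_cell
#' @return List of `unmix_result`, one per cell, named by `cell_id`.
#' @export
unmix_set <- function(spectra, library, mode = c("nnls", "ls"),
                      remove_bg = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(spectra, "spectrum_set"))
  tw <- trim_windows(spectra)
  Ya <- tw$amide$intensity
  Ys <- tw$silent$intensity
  if (remove_bg) {
    Ya <- apply(Ya, 2, function(y) {
      remove_background(tw$amide$wavenumber, y)$corrected
    })
    Ys <- apply(Ys, 2, function(y) {
      remove_background(tw$silent$wavenumber, y)$corrected
    })
  }
  ua <- unmix_window(Ya, library$M_amide, mode)
  us <- unmix_window(Ys, library$M_silent, mode)
  Ra <- library$M_amide %*% ua$theta
  Rs <- library$M_silent %*% us$theta
  out <- lapply(seq_len(ncol(Ya)), function(j) {
    structure(list(
      cell_id = spectra$cell_id[j],
      theta_amide = ua$theta[, j], theta_silent = us$theta[, j],
      residual = list(amide = ua$residual[, j], silent = us$residual[, j]),
      reconstruction = list(amide = as.numeric(Ra[, j]),
                            silent = as.numeric(Rs[, j]),
                            grid_amide = library$grid_amide,
                            grid_silent = library$grid_silent),
      fidelity_r = reconstruction_fidelity(c(Ya[, j], Ys[, j]),
                                           c(Ra[, j], Rs[, j])),
      mode = mode
    ), class = "unmix_result")
  })
  names(out) <- spectra$cell_id
  out
}
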