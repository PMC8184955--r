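#' Construct a set of single-cell Raman spectra
#'
#' A `spectrum_set` holds one wavenumber grid and an intensity matrix with
#' one column per cell, plus per-cell metadata keyed by `cell_id`.
#'
#' @param wavenumber Strictly ascending numeric grid (cm^-1).
#' @param intensity Numeric matrix, `length(wavenumber)` rows, one column per
#'   cell; finite values.
#' @param cell_id Character vector of cell identifiers (default: column
#'   names, else `cell_001` ...).
#' @param meta Optional data frame of per-cell metadata (e.g. `population`);
#'   recycled/keyed by `cell_id`.
#' @return Object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavenumber, intensity, cell_id = NULL, meta = NULL) {
  intensity <- as.matrix(intensity)
  if (length(wavenumber) != nrow(intensity)) {
    stop("length(wavenumber) must equal nrow(intensity)")
  }
  if (is.unsorted(wavenumber, strictly = TRUE)) {
    stop("wavenumber grid must be strictly ascending")
  }
  if (ncol(intensity) > 0 && !all(is.finite(intensity))) {
    bad <- which(!is.finite(intensity), arr.ind = TRUE)[1, ]
    stop("non-finite intensity at row ", bad[1], ", cell column ", bad[2])
  }
  if (is.null(cell_id)) {
    cell_id <- colnames(intensity) %||%
      sprintf("cell_%03d", seq_len(ncol(intensity)))
  }
  if (length(cell_id) != ncol(intensity)) {
    stop("cell_id length must match the number of spectra")
  }
  colnames(intensity) <- cell_id
  if (is.null(meta)) {
    meta <- data.frame(cell_id = cell_id, stringsAsFactors = FALSE)
  } else {
    meta <- as.data.frame(meta)
    if (is.null(meta$cell_id)) meta$cell_id <- cell_id
    meta <- meta[match(cell_id, meta$cell_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(wavenumber = as.numeric(wavenumber), intensity = intensity,
                 cell_id = cell_id, meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", ncol(x$intensity), " cells x ",
      length(x$wavenumber), " wavenumbers (",
      min(x$wavenumber), "-", max(x$wavenumber), " cm^-1)\n", sep = "")
  if (!is.null(x$meta$population)) {
    print(table(population = x$meta$population))
  }
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) ncol(x$intensity)

#' Subset a spectrum set by cell
#'
#' @param x A `spectrum_set`.
#' @param cells Indices, logical mask, or cell ids.
#' @param ... Ignored.
#' @return A `spectrum_set` with the selected cells.
#' @export
`[.spectrum_set` <- function(x, cells, ...) {
  if (is.character(cells)) cells <- match(cells, x$cell_id)
  spectrum_set(x$wavenumber, x$intensity[, cells, drop = FALSE],
               x$cell_id[cells], x$meta[cells, , drop = FALSE])
}

#' Read / write single-cell spectra as wide CSV
#'
#' Wide layout: first column `wavenumber` (cm^-1), one numeric column per
#' cell, header row mandatory. `read_spectra_csv` validates the grid
#' (strictly ascending, no duplicates) and the numeric body, reporting the
#' first offending location.
#'
#' @param path CSV file path.
#' @param meta Optional per-cell metadata data frame to attach on read.
#' @return `read_spectra_csv`: a [spectrum_set()]. `write_spectra_csv`:
#'   `path`, invisibly.
#' @export
read_spectra_csv <- function(path, meta = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 1 || names(df)[1] != "wavenumber") {
    stop("malformed spectra CSV '", path,
         "': first column must be named 'wavenumber'")
  }
  wn <- df[[1]]
  if (nrow(df) == 0) {
    warning("spectra CSV '", path, "' has a header but no rows; ",
            "returning an empty set")
    return(spectrum_set(numeric(0),
                        matrix(numeric(0), 0, max(ncol(df) - 1, 0)),
                        cell_id = names(df)[-1], meta = meta))
  }
  if (!is.numeric(wn)) stop("malformed spectra CSV: non-numeric wavenumber ",
                            "at row ", which(!grepl("^-?[0-9.eE+-]+$",
                                                    as.character(wn)))[1])
  if (anyDuplicated(wn)) {
    stop("duplicated wavenumber ", wn[duplicated(wn)][1], " at row ",
         which(duplicated(wn))[1], " of '", path, "'")
  }
  if (is.unsorted(wn, strictly = TRUE)) {
    stop("wavenumber column of '", path, "' is not strictly ascending ",
         "(first violation near row ", which(diff(wn) <= 0)[1] + 1, ")")
  }
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1]
      stop("non-numeric value in column '", names(body)[j], "' row ", bad,
           " of '", path, "'")
    }
  }
  if (ncol(body) == 0) {
    warning("spectra CSV '", path, "' has a header but no cell columns; ",
            "returning an empty set")
  }
  spectrum_set(wn, as.matrix(body), meta = meta)
}

#' @rdname read_spectra_csv
#' @param spectra A `spectrum_set`.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectrum_set"))
  df <- data.frame(wavenumber = spectra$wavenumber, spectra$intensity,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
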