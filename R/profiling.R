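#' Assemble the cells x probes feature table
#'
#' Collects unmixed weights into the single-cell feature table: one row per
#' cell, one column per probe channel in fixed panel order. Auxiliary
#' components (the endogenous 12C amide envelope and the polystyrene C=C
#' band) are carried in a side table, not among the probe channels.
#'
#' @param results List of [unmix_cell()] / [unmix_set()] results sharing one
#'   panel.
#' @param panel The [panel_config()] the library was built from.
#' @param labels Optional per-cell population labels (vector, or data frame
#'   with `cell_id` and `population`).
#' @return Object of class `feature_table`: a data frame `cell_id`,
#'   `population`, `fidelity_r`, then one column per probe; attributes
#'   `aux` (auxiliary-channel data frame), `channels` (probe names) and
#'   `mode`.
#' @export
build_feature_table <- function(results, panel, labels = NULL) {
  stopifnot(length(results) >= 0, inherits(panel, "panel_config"))
  probes <- panel_components(panel, role = "probe")
  auxes <- panel_components(panel, role = "auxiliary")
  if (length(results) == 0) {
    tab <- cbind(data.frame(cell_id = character(0),
                            population = character(0),
                            fidelity_r = numeric(0)),
                 stats::setNames(as.data.frame(
                   matrix(numeric(0), 0, length(probes))), probes))
    attr(tab, "aux") <- stats::setNames(as.data.frame(
      matrix(numeric(0), 0, length(auxes))), auxes)
    attr(tab, "channels") <- probes
    attr(tab, "mode") <- NA_character_
    class(tab) <- c("feature_table", class(tab))
    return(tab)
  }
  expected <- c(panel_components(panel, window = "amide"),
                panel_components(panel, window = "silent"))
  W <- t(vapply(results, function(rs) {
    th <- c(rs$theta_amide, rs$theta_silent)
    if (!setequal(names(th), expected)) {
      stop("unmixing results do not all come from the supplied panel ",
           "(component sets differ)")
    }
    th[expected]
  }, numeric(length(expected))))
  cell_id <- vapply(results, function(rs) rs$cell_id %||% NA_character_,
                    character(1))
  if (anyNA(cell_id)) cell_id <- sprintf("cell_%04d", seq_along(results))
  pop <- rep(NA_character_, length(results))
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      pop <- labels$population[match(cell_id, labels$cell_id)]
    } else {
      stopifnot(length(labels) == length(results))
      pop <- as.character(labels)
    }
  }
  tab <- cbind(
    data.frame(cell_id = cell_id, population = pop,
               fidelity_r = vapply(results, `[[`, numeric(1), "fidelity_r"),
               stringsAsFactors = FALSE),
    as.data.frame(W[, probes, drop = FALSE]))
  rownames(tab) <- NULL
  attr(tab, "aux") <- as.data.frame(W[, auxes, drop = FALSE])
  attr(tab, "channels") <- probes
  attr(tab, "mode") <- results[[1]]$mode
  class(tab) <- c("feature_table", class(tab))
  tab
}

#' Probe channel names of a feature table
#' @param table A `feature_table`.
#' @return Character vector of channel names.
#' @export
feature_channels <- function(table) {
  attr(table, "channels") %||%
    setdiff(names(table), c("cell_id", "population", "fidelity_r"))
}

# numeric channel matrix of a feature table
feature_matrix <- function(table, channels = NULL) {
  channels <- channels %||% feature_channels(table)
  missing <- setdiff(channels, names(table))
  if (length(missing)) stop("unknown channel(s): ",
                            paste(missing, collapse = ", "))
  as.matrix(table[, channels, drop = FALSE])
}

#' Normalize a feature table to a control population
#'
#' Divides every channel by the control arm's mean of that channel, so each
#' entry reads as a fold change versus control; also returns the
#' population-mean matrix (arms x channels) used for heatmap display,
#' optionally log2-transformed.
#'
#' @param table A `feature_table` with population labels.
#' @param control_label Name of the control arm.
#' @param log2 Return `population_means` on the log2 scale (default FALSE).
#' @return List `table` (normalized `feature_table`) and
#'   `population_means` (matrix, arms x channels, control row = 1 or 0).
#' @export
normalize_to_control <- function(table, control_label, log2 = FALSE) {
  channels <- feature_channels(table)
  if (!control_label %in% table$population) {
    stop("control population '", control_label, "' not present")
  }
  ctrl <- colMeans(feature_matrix(table)[table$population == control_label, ,
                                         drop = FALSE])
  zero <- channels[ctrl == 0]
  if (length(zero)) {
    stop("control mean is zero in channel(s): ",
         paste(zero, collapse = ", "), "; cannot normalize")
  }
  norm <- table
  norm[channels] <- sweep(feature_matrix(table), 2, ctrl, "/")
  pops <- unique(table$population)
  pm <- t(vapply(pops, function(p) {
    colMeans(as.matrix(norm[norm$population == p, channels, drop = FALSE]))
  }, numeric(length(channels))))
  dimnames(pm) <- list(pops, channels)
  if (log2) pm <- base::log2(pm)
  list(table = norm, population_means = pm)
}

#' Per-channel fold change of a treated arm versus control
#'
#' mean(treated) / mean(control) per channel -- the quantity displayed on
#' one axis of a fold-change radar diagram.
#'
#' @param table A `feature_table`.
#' @param treated_label,control_label Arm names.
#' @param channels Channels to report (default: all probe channels).
#' @return Named numeric vector of fold changes.
#' @export
fold_change_radar <- function(table, treated_label, control_label,
                              channels = NULL) {
  channels <- channels %||% feature_channels(table)
  X <- feature_matrix(table, channels)
  for (lab in c(treated_label, control_label)) {
    if (!lab %in% table$population) stop("population '", lab,
                                         "' not present")
  }
  m_t <- colMeans(X[table$population == treated_label, , drop = FALSE])
  m_c <- colMeans(X[table$population == control_label, , drop = FALSE])
  m_t / m_c
}

#' Plot a fold-change radar diagram
#'
#' @param fold Named fold-change vector from [fold_change_radar()].
#' @param main Title.
#' @param ref Reference ring value (default 1 = control level).
#' @return Invisibly, the plotted coordinates.
#' @export
plot_radar <- function(fold, main = "fold change vs control", ref = 1) {
  k <- length(fold)
  ang <- pi / 2 - 2 * pi * (seq_len(k) - 1) / k
  rmax <- max(fold, ref) * 1.15
  graphics::plot(0, 0, type = "n", xlim = c(-rmax, rmax),
                 ylim = c(-rmax, rmax), axes = FALSE, xlab = "", ylab = "",
                 main = main, asp = 1)
  for (rr in pretty(c(0, rmax), 4)[-1]) {
    graphics::polygon(rr * cos(ang), rr * sin(ang), border = "grey85")
  }
  graphics::polygon(ref * cos(ang), ref * sin(ang), border = "grey40",
                    lty = 2)
  graphics::segments(0, 0, rmax * cos(ang), rmax * sin(ang),
                     col = "grey85")
  graphics::polygon(fold * cos(ang), fold * sin(ang),
                    border = "firebrick",
                    col = grDevices::adjustcolor("firebrick", 0.3))
  graphics::text(rmax * 1.05 * cos(ang), rmax * 1.05 * sin(ang),
                 names(fold), cex = 0.8, xpd = NA)
  invisible(data.frame(channel = names(fold), fold = fold,
                       x = fold * cos(ang), y = fold * sin(ang)))
}

#' Box-plot statistics and a two-group test for one channel
#'
#' Box statistics use the half-IQR whisker convention: whiskers reach the
#' lowest and highest data within 0.5 x IQR of the first and third
#' quartiles. When exactly two groups are requested, a two-sided location
#' test between them is included (Mann--Whitney U by default -- robust to
#' the log-normal skew of intensity data -- or Welch's t-test).
#'
#' @param table A `feature_table`.
#' @param channel Channel name.
#' @param groups Character vector of population names (default: all).
#' @param test `"wilcox"` (default) or `"welch"`.
#' @return List `stats` (data frame: group, channel, n, median, q1, q3,
#'   lo_whisker, hi_whisker) and, for two groups, `p_value` and `test`.
#' @export
group_stats <- function(table, channel, groups = NULL,
                        test = c("wilcox", "welch")) {
  test <- match.arg(test)
  groups <- groups %||% unique(table$population)
  absent <- setdiff(groups, table$population)
  if (length(absent)) stop("group(s) absent from the table: ",
                           paste(absent, collapse = ", "))
  x <- feature_matrix(table, channel)[, 1]
  vals <- lapply(groups, function(g) x[table$population == g])
  if (any(lengths(vals) < 3)) stop("each group needs n >= 3")
  st <- do.call(rbind, lapply(seq_along(groups), function(i) {
    v <- vals[[i]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo_cut <- q[1] - 0.5 * iqr
    hi_cut <- q[3] + 0.5 * iqr
    data.frame(group = groups[i], channel = channel, n = length(v),
               median = q[2], q1 = q[1], q3 = q[3],
               lo_whisker = min(v[v >= lo_cut]),
               hi_whisker = max(v[v <= hi_cut]),
               stringsAsFactors = FALSE)
  }))
  out <- list(stats = st)
  if (length(groups) == 2) {
    out$test <- test
    out$p_value <- if (test == "wilcox") {
      stats::wilcox.test(vals[[1]], vals[[2]], exact = FALSE)$p.value
    } else {
      stats::t.test(vals[[1]], vals[[2]])$p.value
    }
  }
  out
}

#' Write a feature table (probe channels + auxiliaries) as CSV
#'
#' @param table A `feature_table`.
#' @param path CSV path.
#' @param include_aux Append the auxiliary channels as extra columns
#'   prefixed `aux_` (default TRUE).
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path, include_aux = TRUE) {
  df <- as.data.frame(table)
  aux <- attr(table, "aux")
  if (include_aux && !is.null(aux) && ncol(aux) > 0) {
    names(aux) <- paste0("aux_", names(aux))
    df <- cbind(df, aux)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
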