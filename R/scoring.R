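#' Assign 5-level scores to a size-response curve
#'
#' Equal-width value bins between `value_range[1]` and `value_range[2]`
#' (default the curve's own min/max): level k covers the k-th bin, so the
#' assignment is monotone in the behavior value. Equal-width (rather than
#' quantile) binning preserves amplitude differences, which is what makes
#' cross-cell-type mechanosensitivity visible when a shared `value_range`
#' is used for all cell types ("same standards").
#'
#' A zero-range input collapses to all level 1 with a warning.
#'
#' @param curve a `size_response_curve` (or a numeric vector of values).
#' @param n_levels number of levels (default 5).
#' @param value_range optional c(min, max) shared scoring range.
#' @return the curve with an integer `level` column (or an integer vector
#'   for vector input).
#' @export
discretize_levels <- function(curve, n_levels = 5L, value_range = NULL) {
  stopifnot(n_levels >= 2L)
  v <- if (is.numeric(curve)) curve else curve$mean
  if (is.null(value_range)) value_range <- range(v, na.rm = TRUE)
  span <- diff(value_range)
  if (!is.finite(span) || span <= 0) {
    warning("zero value range: all levels set to 1")
    lev <- rep(1L, length(v))
  } else {
    lev <- 1L + pmin(n_levels - 1L,
                     pmax(0L, floor((v - value_range[1L]) / span * n_levels)))
    lev[!is.finite(v)] <- NA_integer_
  }
  if (is.numeric(curve)) return(lev)
  curve$level <- lev
  attr(curve, "value_range") <- value_range
  attr(curve, "n_levels") <- n_levels
  curve
}

#' Stack leveled curves into a radar table for one cell type
#'
#' @param curves named list of `size_response_curve`s (one per behavior),
#'   all sharing identical size-bin edges; curves without a `level` column
#'   are discretized with their own range.
#' @param cell_type label.
#' @param n_levels levels used when discretizing.
#' @param value_ranges optional named list of shared per-behavior scoring
#'   ranges (names matching `names(curves)`).
#' @return a `radar_table`: integer matrix (behaviors x size bins) with
#'   attributes `cell_type`, `bin_edges`, `n_levels`.
#' @export
build_radar_table <- function(curves, cell_type = NA_character_,
                              n_levels = 5L, value_ranges = NULL) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  if (is.null(names(curves)))
    names(curves) <- vapply(curves, function(c)
      attr(c, "behavior_name") %||% "behavior", "")
  edges <- attr(curves[[1L]], "bin_edges")
  for (c in curves) {
    e <- attr(c, "bin_edges")
    if (is.null(e) || is.null(edges) || length(e) != length(edges) ||
        any(abs(e - edges) > 1e-9 * max(edges)))
      stop("mismatched size-bin edges across curves")
  }
  levs <- lapply(names(curves), function(b) {
    c <- curves[[b]]
    if (!"level" %in% names(c))
      c <- discretize_levels(c, n_levels = n_levels,
                             value_range = value_ranges[[b]])
    c$level
  })
  m <- do.call(rbind, levs)
  rownames(m) <- names(curves)
  colnames(m) <- sprintf("bin%d", seq_len(ncol(m)))
  structure(m, class = c("radar_table", class(m)), cell_type = cell_type,
            bin_edges = edges, n_levels = n_levels)
}

#' Optimal feature size of a response curve
#'
#' The centre of the bin with the largest mean response; ties resolve to
#' the smallest size. Invariant under strictly monotone transforms of the
#' behavior values.
#'
#' @param curve a `size_response_curve`.
#' @return list with `size_um` (geometric bin centre), `bin`, `value` and
#'   `level` (if present).
#' @export
optimal_feature_size <- function(curve) {
  stopifnot(nrow(curve) >= 1L)
  k <- which.max(curve$mean)     # first maximum = smallest size on ties
  list(size_um = curve$size_mid_um[k], bin = curve$bin[k],
       value = curve$mean[k],
       level = if ("level" %in% names(curve)) curve$level[k] else NA_integer_)
}

#' Mechanosensitivity index of a radar table
#'
#' Per behavior, the range of levels across size bins (0 to
#' `n_levels - 1`); overall, the mean across behaviors. Higher values mean
#' the cell type responds more strongly to changing topography; an
#' impaired-mechanosensitivity type scores low. Location-invariant by
#' construction (adding a constant to all behavior values shifts levels
#' only through the shared scoring range, leaving ranges unchanged).
#'
#' @param table a `radar_table`.
#' @return list with `per_behavior` (named numeric) and `overall`.
#' @export
sensitivity_index <- function(table) {
  stopifnot(inherits(table, "radar_table"))
  per <- apply(table, 1L, function(r) diff(range(r, na.rm = TRUE)))
  list(per_behavior = per, overall = mean(per))
}

#' Compare radar tables across cell types
#'
#' @param tables named list of >= 2 `radar_table`s with identical binning.
#' @return a `cell_type_comparison`: list with `optimal` (data.frame of
#'   per-type, per-behavior best size bin), `sensitivity` (per-type
#'   indices), and `pairwise` (level-difference matrices, type A minus
#'   type B), in deterministic (alphabetical) type order.
#' @export
compare_cell_types <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("need at least 2 radar tables to compare")
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t)
      attr(t, "cell_type") %||% "type", "")
  tables <- tables[order(names(tables))]
  e1 <- attr(tables[[1L]], "bin_edges")
  for (t in tables) {
    e <- attr(t, "bin_edges")
    if (!identical(dim(t), dim(tables[[1L]])) ||
        !identical(rownames(t), rownames(tables[[1L]])) ||
        length(e) != length(e1) || any(abs(e - e1) > 1e-9 * max(e1)))
      stop("radar tables have mismatched binning")
  }
  mids <- sqrt(e1[-1L] * e1[-length(e1)])
  optimal <- do.call(rbind, lapply(names(tables), function(ty) {
    t <- tables[[ty]]
    data.frame(cell_type = ty, behavior = rownames(t),
               best_bin = apply(t, 1L, which.max),
               best_size_um = mids[apply(t, 1L, which.max)],
               row.names = NULL)
  }))
  sens <- do.call(rbind, lapply(names(tables), function(ty) {
    s <- sensitivity_index(tables[[ty]])
    data.frame(cell_type = ty, t(s$per_behavior), overall = s$overall,
               row.names = NULL, check.names = FALSE)
  }))
  prs <- utils::combn(names(tables), 2L, simplify = FALSE)
  pairwise <- lapply(prs, function(p) {
    unclass(tables[[p[1L]]]) - unclass(tables[[p[2L]]])
  })
  names(pairwise) <- vapply(prs, paste, "", collapse = " - ")
  structure(list(optimal = optimal, sensitivity = sens, pairwise = pairwise),
            class = "cell_type_comparison")
}

#' @export
print.cell_type_comparison <- function(x, ...) {
  cat("Cell-type comparison\n\nPer-behavior optimal sizes:\n")
  print(x$optimal)
  cat("\nSensitivity indices:\n")
  print(x$sensitivity)
  invisible(x)
}

#' Pooled per-behavior scoring ranges across cell types
#'
#' The "same standards" rule: one value range per behavior, pooled over
#' every cell type's curve, so level assignments are comparable across
#' types.
#'
#' @param curves_by_type list (cell type) of named lists (behavior) of
#'   `size_response_curve`s.
#' @return named list of c(min, max) per behavior.
#' @export
shared_value_ranges <- function(curves_by_type) {
  behaviors <- names(curves_by_type[[1L]])
  out <- lapply(behaviors, function(b) {
    vals <- unlist(lapply(curves_by_type, function(ct) ct[[b]]$mean))
    range(vals, na.rm = TRUE)
  })
  names(out) <- behaviors
  out
}
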