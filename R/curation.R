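#' Flag clone-border cells
#'
#' A cell is on a clone border iff any of its Delaunay neighbors (after the
#' same edge-length quantile filter used by the cell graph, so "neighbor"
#' means the same thing in both places) carries a different dosage. The
#' relation is symmetric by construction.
#'
#' @param positions Two-column matrix of cell centroids.
#' @param dosages Integer dosage per cell (no missing values).
#' @param edge_quantile Delaunay edge-length filter quantile.
#' @return Logical vector, `TRUE` for border cells.
#' @export
flag_borders <- function(positions, dosages, edge_quantile = 0.95) {
  if (any(is.na(dosages))) {
    qm_stop("all cells must have an assigned dosage",
            "qmosaic_precondition_error")
  }
  edges <- delaunay_edges(positions, edge_quantile)
  border <- rep(FALSE, length(dosages))
  diff <- dosages[edges$i] != dosages[edges$j]
  border[edges$i[diff]] <- TRUE
  border[edges$j[diff]] <- TRUE
  border
}

#' Restrict a measurement table to a region of interest
#'
#' Keeps rows whose centroid lies inside the polygon (even-odd rule;
#' boundary points count as inside) and, if given, within the x interval.
#' An x-window alone (roi = NULL) restricts to cells of comparable position
#' along the anterior-posterior axis, e.g. a band of similar developmental
#' age near the morphogenetic furrow.
#'
#' @param table A [measurement_table()].
#' @param roi Two-column matrix of polygon vertices, or `NULL`.
#' @param x_window Optional `c(xmin, xmax)` interval.
#' @return The filtered table.
#' @export
apply_roi <- function(table, roi = NULL, x_window = NULL) {
  table <- measurement_table(table)
  keep <- rep(TRUE, nrow(table))
  if (!is.null(roi)) {
    roi <- as.matrix(roi)
    if (!polygon_is_simple(roi)) {
      qm_stop("roi polygon is self-intersecting", "qmosaic_geometry_error")
    }
    keep <- keep & point_in_polygon(table$x, table$y, roi)
  }
  if (!is.null(x_window)) {
    keep <- keep & table$x >= x_window[1] & table$x <= x_window[2]
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  measurement_table(out)
}

#' Compare reporter levels between dosage groups
#'
#' Two-sided Mann-Whitney U test on the (corrected, if available) reporter
#' levels of two dosage groups, optionally excluding clone-border cells.
#' The exact null distribution is used when both groups have at most 20
#' observations and the data are tie-free; otherwise the normal
#' approximation with tie correction applies. The reported U is the smaller
#' of the two orientations, so `0 <= U <= n_a * n_b / 2`.
#'
#' @param table An annotated [measurement_table()].
#' @param channel Reporter channel (raw column name; its `_corrected`
#'   column is used when present).
#' @param group_a,group_b Dosage labels to compare.
#' @param exclude_borders Drop cells flagged as clone borders (requires a
#'   `border` column).
#' @return A `comparison_result` list: `group_a`, `group_b`, `n_a`, `n_b`,
#'   `U`, `p`.
#' @export
compare_clones <- function(table, channel, group_a, group_b,
                           exclude_borders = TRUE) {
  table <- measurement_table(table)
  if (!"dosage" %in% names(table)) {
    qm_stop("table has no dosage labels", "qmosaic_precondition_error")
  }
  if (exclude_borders) {
    if (!"border" %in% names(table)) {
      qm_stop("exclude_borders = TRUE but table has no border column",
              "qmosaic_precondition_error")
    }
    table <- table[!is.na(table$border) & !table$border, , drop = FALSE]
  }
  col <- intensity_column(table, channel)
  a <- table[[col]][!is.na(table$dosage) & table$dosage == group_a]
  b <- table[[col]][!is.na(table$dosage) & table$dosage == group_b]
  if (length(a) == 0 || length(b) == 0) {
    qm_stop("empty dosage group after filtering",
            "qmosaic_insufficient_data_error")
  }
  exact <- length(a) <= 20 && length(b) <= 20 &&
    !any(duplicated(c(a, b)))
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = !exact))
  U <- unname(ht$statistic)
  U <- min(U, length(a) * length(b) - U)
  structure(list(group_a = group_a, group_b = group_b,
                 n_a = length(a), n_b = length(b),
                 U = U, p = ht$p.value, exact = exact),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U (%s): dosage %s (n=%d) vs %s (n=%d)\n",
              if (x$exact) "exact" else "normal approx.",
              x$group_a, x$n_a, x$group_b, x$n_b))
  cat(sprintf("  U = %g, two-sided p = %.4g\n", x$U, x$p))
  invisible(x)
}
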