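# Grade-transition accounting: class-by-class area matrices between epochs and
# every derived statistic (net change, inflow/outflow shares, changed area,
# grade-area summaries, Sankey export).

#' Construct a transition matrix from an area matrix
#'
#' Entry `s_ij` is the area (km^2) moving from class `i` at the start epoch to
#' class `j` at the end epoch. Totals are derived; used directly this lets a
#' published transition table be analysed without rasters.
#'
#' @param area K x K non-negative numeric matrix.
#' @param labels Class names, in matrix order.
#' @return An object of class `fvc_transition_matrix` with `area`, `labels`,
#'   `row_totals`, `col_totals`, `grand_total`.
#' @export
transition_matrix_from_area <- function(area, labels = rownames(area)) {
  area <- as.matrix(area)
  if (nrow(area) != ncol(area)) stop("area matrix must be square")
  if (any(area < 0)) stop("areas must be non-negative")
  if (is.null(labels)) labels <- paste0("class_", seq_len(nrow(area)))
  dimnames(area) <- list(labels, labels)
  structure(list(area = area, labels = labels,
                 row_totals = rowSums(area), col_totals = colSums(area),
                 grand_total = sum(area)),
            class = "fvc_transition_matrix")
}

#' @export
print.fvc_transition_matrix <- function(x, ...) {
  cat(sprintf("<fvc_transition_matrix> %d classes, total %.2f km^2\n",
              length(x$labels), x$grand_total))
  print(round(x$area, 2))
  invisible(x)
}

#' Transition matrix between two classified rasters
#'
#' Cross-tabulates start and end class per pixel and scales counts by the
#' nominal cell area. Pixels masked in either epoch are excluded.
#'
#' @param start,end Co-registered `fvc_classified` grids sharing one class
#'   dictionary.
#' @param cell_area_km2 Area of one cell in km^2 (250 m cells: 0.0625).
#' @return An `fvc_transition_matrix`.
#' @export
transition_matrix <- function(start, end, cell_area_km2 = 0.0625) {
  if (!identical(dim(start$values), dim(end$values)) ||
      !same_geometry(start, end))
    stop("start and end grids are not co-registered")
  if (!identical(start$labels, end$labels))
    stop("start and end class dictionaries differ")
  if (cell_area_km2 <= 0) stop("cell_area_km2 must be positive")
  k <- length(start$labels)
  keep <- !start$mask & !end$mask
  s <- factor(start$values[keep], levels = seq_len(k))
  e <- factor(end$values[keep], levels = seq_len(k))
  counts <- table(s, e)
  transition_matrix_from_area(unclass(counts) * cell_area_km2, start$labels)
}

#' Net area change of a class across a transition
#'
#' Column total (area holding the class at the end) minus row total (at the
#' start); negative values are net declines.
#'
#' @param tm An `fvc_transition_matrix`.
#' @param class_label Class name.
#' @return Signed km^2.
#' @export
net_change <- function(tm, class_label) {
  if (!class_label %in% tm$labels) stop("unknown class label: ", class_label)
  unname(tm$col_totals[class_label] - tm$row_totals[class_label])
}

#' Outflow or inflow shares of a class
#'
#' For `outflow`, the percentage split of the class's off-diagonal row (where
#' its lost area went); for `inflow`, of its off-diagonal column (where its
#' gained area came from). Shares sum to 100.
#'
#' @param tm An `fvc_transition_matrix`.
#' @param class_label Class name.
#' @param direction `"outflow"` or `"inflow"`.
#' @return Named numeric vector of percentages over the other classes.
#' @export
flow_shares <- function(tm, class_label, direction = c("outflow", "inflow")) {
  direction <- match.arg(direction)
  if (!class_label %in% tm$labels) stop("unknown class label: ", class_label)
  i <- match(class_label, tm$labels)
  flows <- if (direction == "outflow") tm$area[i, -i] else tm$area[-i, i]
  tot <- sum(flows)
  if (tot <= 0) {
    warning("class '", class_label, "' has zero off-diagonal ", direction)
    return(stats::setNames(numeric(0), character(0)))
  }
  100 * flows / tot
}

#' Total inter-class (changed) area of a transition
#'
#' Sum of the off-diagonal entries — area that switched grade, excluding
#' intra-grade persistence. `changed_area + trace = grand_total`.
#'
#' @param tm An `fvc_transition_matrix`.
#' @return km^2.
#' @export
changed_area <- function(tm) {
  sum(tm$area) - sum(diag(tm$area))
}

#' Area and percentage per class of a classified raster
#'
#' @param classified An `fvc_classified` grid, or a named numeric vector of
#'   areas (km^2) per class for table-driven use.
#' @param cell_area_km2 Cell area (ignored for the vector form).
#' @return Data frame with `class`, `area_km2`, `percentage` (of the unmasked
#'   total; sums to 100).
#' @export
grade_area_summary <- function(classified, cell_area_km2 = 0.0625) {
  if (inherits(classified, "fvc_classified")) {
    k <- length(classified$labels)
    counts <- tabulate(classified$values[!classified$mask], nbins = k)
    areas <- stats::setNames(counts * cell_area_km2, classified$labels)
  } else {
    areas <- classified
    if (is.null(names(areas))) stop("area vector must be named by class")
  }
  data.frame(class = names(areas), area_km2 = unname(areas),
             percentage = unname(100 * areas / sum(areas)),
             row.names = NULL)
}

#' Long-format flow table for Sankey rendering
#'
#' One row per (epoch, source class, target class) with its area; consecutive
#' matrices must share the class dictionary.
#'
#' @param tms List of `fvc_transition_matrix`, in epoch order.
#' @param epoch_labels Optional labels, one per matrix.
#' @return Data frame with `epoch`, `from`, `to`, `area_km2`.
#' @export
export_sankey <- function(tms, epoch_labels = NULL) {
  if (!length(tms)) stop("no transition matrices supplied")
  labs <- tms[[1]]$labels
  for (tm in tms) if (!identical(tm$labels, labs))
    stop("transition matrices do not share class labels")
  if (is.null(epoch_labels)) epoch_labels <- paste0("epoch_", seq_along(tms))
  do.call(rbind, lapply(seq_along(tms), function(i) {
    a <- tms[[i]]$area
    data.frame(epoch = epoch_labels[i],
               from = rep(labs, times = length(labs)),
               to = rep(labs, each = length(labs)),
               area_km2 = as.vector(a),
               row.names = NULL)
  }))
}
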