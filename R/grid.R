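#' @useDynLib fvcdyn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile median sd cor pf pt pnorm rnorm runif var lm coef
#' @importFrom utils head tail write.csv read.csv
NULL

# ---------------------------------------------------------------------------
# Grid: a single georeferenced raster layer.
#
# values   : numeric matrix, row 1 = northernmost row
# transform: list(x0, y0, dx, dy) — (x0, y0) is the CENTER of the top-left
#            cell (pixel-center registration); dx = cell width (east),
#            dy = cell height (southward step); both strictly positive
# mask     : logical matrix, TRUE where the cell is nodata
# ---------------------------------------------------------------------------

#' Construct a raster grid
#'
#' The core single-layer container of the package: a numeric matrix with an
#' affine pixel-center georeference and a nodata mask. Row 1 is the
#' northernmost row. All raster operations in the package ignore masked cells
#' and propagate the mask to their outputs.
#'
#' @param values Numeric matrix; row 1 is the northernmost row.
#' @param transform List with elements `x0`, `y0` (projected coordinates of the
#'   center of the top-left cell), `dx` (cell width, > 0) and `dy` (cell
#'   height, > 0; rows step southward by `dy`).
#' @param mask Logical matrix of the same shape; `TRUE` marks nodata cells.
#'   Non-finite `values` are always masked in addition.
#' @param units Free-text unit tag.
#' @param crs_tag Free-text coordinate-reference identifier.
#' @return An object of class `fvc_grid`.
#' @export
new_grid <- function(values, transform = list(x0 = 0, y0 = 0, dx = 250, dy = 250),
                     mask = NULL, units = "", crs_tag = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- matrix(FALSE, nrow(values), ncol(values))
  mask <- mask | !is.finite(values)
  stopifnot(identical(dim(values), dim(mask)))
  tr <- as.list(transform)[c("x0", "y0", "dx", "dy")]
  if (any(vapply(tr, is.null, logical(1))))
    stop("transform must supply x0, y0, dx, dy")
  if (tr$dx <= 0 || tr$dy <= 0) stop("cell dimensions must be strictly positive")
  structure(list(values = values, transform = tr, mask = mask,
                 units = units, crs_tag = crs_tag),
            class = "fvc_grid")
}

#' @export
print.fvc_grid <- function(x, ...) {
  cat(sprintf("<fvc_grid> %d x %d cells, %.6g x %.6g spacing, %d masked\n",
              nrow(x$values), ncol(x$values), x$transform$dx, x$transform$dy,
              sum(x$mask)))
  invisible(x)
}

#' @export
dim.fvc_grid <- function(x) dim(x$values)

#' Grid geometry specification
#'
#' Extracts (or builds) the geometry a resampling / interpolation target needs:
#' shape plus affine transform, without values.
#'
#' @param x An `fvc_grid`, or `NULL` to build from the remaining arguments.
#' @param nrows,ncols,x0,y0,dx,dy Geometry fields when `x` is `NULL`.
#' @return A list with `nrows`, `ncols`, `x0`, `y0`, `dx`, `dy`.
#' @export
grid_geometry <- function(x = NULL, nrows = NULL, ncols = NULL,
                          x0 = 0, y0 = 0, dx = 250, dy = 250) {
  if (!is.null(x)) {
    if (inherits(x, "fvc_grid"))
      return(list(nrows = nrow(x$values), ncols = ncol(x$values),
                  x0 = x$transform$x0, y0 = x$transform$y0,
                  dx = x$transform$dx, dy = x$transform$dy))
    if (is.list(x) && all(c("nrows", "ncols", "x0", "y0", "dx", "dy") %in% names(x)))
      return(x[c("nrows", "ncols", "x0", "y0", "dx", "dy")])
    stop("cannot interpret grid geometry")
  }
  list(nrows = nrows, ncols = ncols, x0 = x0, y0 = y0, dx = dx, dy = dy)
}

# projected coordinates of all cell centers of a geometry
geom_cell_centers <- function(geom) {
  list(x = geom$x0 + (seq_len(geom$ncols) - 1) * geom$dx,
       y = geom$y0 - (seq_len(geom$nrows) - 1) * geom$dy)
}

same_geometry <- function(a, b, tol = 1e-9) {
  ga <- grid_geometry(a); gb <- grid_geometry(b)
  ga$nrows == gb$nrows && ga$ncols == gb$ncols &&
    all(abs(unlist(ga[c("x0", "y0", "dx", "dy")]) -
            unlist(gb[c("x0", "y0", "dx", "dy")])) < tol)
}

#' Unmasked values of a grid
#' @param grid An `fvc_grid`.
#' @return Numeric vector of the values at unmasked cells.
#' @export
grid_values <- function(grid) grid$values[!grid$mask]

# ---------------------------------------------------------------------------
# ClassifiedGrid: integer-labelled grid + class dictionary
# ---------------------------------------------------------------------------

#' Construct a classified (integer-labelled) grid
#'
#' @param values Integer matrix of class codes in `1..length(labels)`.
#' @param labels Character vector naming the classes, in code order.
#' @inheritParams new_grid
#' @return An object of classes `fvc_classified` and `fvc_grid`.
#' @export
new_classified_grid <- function(values, labels, transform = list(x0 = 0, y0 = 0, dx = 250, dy = 250),
                                mask = NULL, units = "class", crs_tag = "") {
  g <- new_grid(values, transform, mask, units, crs_tag)
  codes <- g$values[!g$mask]
  if (length(codes) && (any(codes %% 1 != 0) || any(codes < 1) || any(codes > length(labels))))
    stop("class codes must be integers in 1..length(labels)")
  g$labels <- as.character(labels)
  class(g) <- c("fvc_classified", "fvc_grid")
  g
}

#' @export
print.fvc_classified <- function(x, ...) {
  cat(sprintf("<fvc_classified> %d x %d cells, %d classes: %s\n",
              nrow(x$values), ncol(x$values), length(x$labels),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# GridStack: time-ordered co-registered layers stored as a 3-D array
# ---------------------------------------------------------------------------

#' Construct a time-ordered stack of co-registered grids
#'
#' @param grids A list of `fvc_grid` sharing shape and transform, or a 3-D
#'   array `[row, col, time]`.
#' @param years Integer vector of years, one per layer.
#' @param months Optional integer vector of months (NA for annual layers).
#' @param periods Optional integer sub-month period index (for e.g. 16-day
#'   composites; NA when the native step is monthly).
#' @param transform,mask,units,crs_tag As in [new_grid()]; used when `grids`
#'   is an array (`mask` then a 3-D logical array).
#' @return An object of class `fvc_gridstack` holding a 3-D `data` array, a
#'   3-D `mask`, the shared transform and a `times` data frame.
#' @export
grid_stack <- function(grids, years, months = NA, periods = NA,
                       transform = NULL, mask = NULL, units = "", crs_tag = "") {
  if (is.list(grids) && !is.array(grids)) {
    stopifnot(length(grids) >= 1)
    tr <- grids[[1]]$transform
    for (g in grids) {
      if (!identical(dim(g$values), dim(grids[[1]]$values)) ||
          !same_geometry(g, grids[[1]]))
        stop("all stack members must share shape and transform")
    }
    data <- array(unlist(lapply(grids, `[[`, "values")),
                  dim = c(dim(grids[[1]]$values), length(grids)))
    msk <- array(unlist(lapply(grids, `[[`, "mask")),
                 dim = dim(data))
    units <- grids[[1]]$units; crs_tag <- grids[[1]]$crs_tag
  } else {
    data <- grids
    stopifnot(length(dim(data)) == 3)
    tr <- as.list(transform)[c("x0", "y0", "dx", "dy")]
    msk <- if (is.null(mask)) array(FALSE, dim(data)) else mask
  }
  msk <- msk | !is.finite(data)
  nt <- dim(data)[3]
  times <- data.frame(year = rep_len(as.integer(years), nt),
                      month = rep_len(as.integer(months), nt),
                      period = rep_len(as.integer(periods), nt))
  key <- times$year * 10000 + ifelse(is.na(times$month), 0L, times$month) * 100 +
    ifelse(is.na(times$period), 0L, times$period)
  if (nt > 1 && any(diff(key) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(data = data, mask = msk, transform = tr, times = times,
                 units = units, crs_tag = crs_tag),
            class = "fvc_gridstack")
}

#' @export
print.fvc_gridstack <- function(x, ...) {
  cat(sprintf("<fvc_gridstack> %d x %d cells, %d layers (%d-%d)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times$year), max(x$times$year)))
  invisible(x)
}

#' Extract one layer of a stack as a grid
#' @param stack An `fvc_gridstack`.
#' @param i Layer index.
#' @return An `fvc_grid`.
#' @export
stack_layer <- function(stack, i) {
  new_grid(stack$data[, , i], stack$transform, stack$mask[, , i],
           stack$units, stack$crs_tag)
}

#' Number of layers in a stack
#' @param stack An `fvc_gridstack`.
#' @return Integer layer count.
#' @export
stack_size <- function(stack) dim(stack$data)[3]

# ---------------------------------------------------------------------------
# CSV grid dialect I/O
#
# Plain-text, diffable raster format used for fixtures and outputs:
#   #fvcdyn_grid v1
#   #shape <nrows> <ncols>
#   #transform <x0> <y0> <dx> <dy>
#   #nodata <value>
#   #units <text>
#   #crs <text>
#   <row 1, comma-separated, northernmost first>
#   ...
# ---------------------------------------------------------------------------

#' Read a grid from the package's CSV grid dialect
#'
#' The on-disk format is a plain-text, diffable raster: `#`-prefixed header
#' lines carrying shape, affine transform (pixel-center registration) and the
#' declared nodata value, followed by comma-separated rows north to south.
#' Cells equal to the nodata value are masked.
#'
#' @param path Path to a `.csv` grid file.
#' @return An `fvc_grid`.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 4 || !startsWith(lines[1], "#fvcdyn_grid"))
    stop("not a recognised grid file (missing header): ", path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  take <- function(key) {
    ln <- grep(paste0("^#", key, "( |$)"), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^#", key, " ?"), "", ln[1])
  }
  shp_s <- take("shape"); trv_s <- take("transform")
  if (is.null(shp_s) || is.null(trv_s))
    stop("missing shape/geotransform header in ", path)
  shp <- as.integer(strsplit(shp_s, "\\s+")[[1]])
  trv <- as.numeric(strsplit(trv_s, "\\s+")[[1]])
  if (length(shp) != 2 || length(trv) != 4)
    stop("malformed geotransform header in ", path)
  nodata <- as.numeric(take("nodata"))
  units <- take("units"); if (is.null(units)) units <- ""
  crs_tag <- take("crs"); if (is.null(crs_tag)) crs_tag <- ""
  rows <- lapply(body[nzchar(body)], function(l) as.numeric(strsplit(l, ",")[[1]]))
  if (length(rows) != shp[1] || any(lengths(rows) != shp[2]))
    stop("grid body does not match declared shape in ", path)
  values <- do.call(rbind, rows)
  mask <- if (is.finite(nodata)) values == nodata else matrix(FALSE, shp[1], shp[2])
  values[mask] <- NA_real_
  new_grid(values, list(x0 = trv[1], y0 = trv[2], dx = trv[3], dy = trv[4]),
           mask, units, crs_tag)
}

#' Write a grid in the CSV grid dialect
#'
#' Masked cells are stored as the declared nodata value; the transform is
#' preserved exactly. [read_grid()] inverts the operation.
#'
#' @param grid An `fvc_grid`.
#' @param path Output path.
#' @param nodata Nodata value to store masked cells as.
#' @param digits Significant digits written for cell values.
#' @return Invisibly, `path`.
#' @export
write_grid <- function(grid, path, nodata = -9999, digits = 10) {
  v <- grid$values
  v[grid$mask] <- nodata
  hdr <- c("#fvcdyn_grid v1",
           sprintf("#shape %d %d", nrow(v), ncol(v)),
           sprintf("#transform %.10g %.10g %.10g %.10g",
                   grid$transform$x0, grid$transform$y0,
                   grid$transform$dx, grid$transform$dy),
           sprintf("#nodata %.10g", nodata),
           paste("#units", grid$units),
           paste("#crs", grid$crs_tag))
  body <- apply(v, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                        collapse = ","))
  ok <- tryCatch({
    writeLines(c(hdr, body), path); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write grid file: ", path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Resampling / co-registration
# ---------------------------------------------------------------------------

#' Resample a grid onto a target geometry
#'
#' Nearest-neighbour or bilinear resampling onto another pixel-center grid
#' geometry. Bilinear output is a convex combination of the four surrounding
#' source cell centers (edge cells clamp to the source extent); nearest never
#' invents values absent from the source and is mandatory for categorical
#' layers. A target cell is masked whenever any source cell it draws from is
#' masked (nodata propagation).
#'
#' @param grid Source `fvc_grid`.
#' @param target Target geometry: an `fvc_grid` or a [grid_geometry()] list.
#' @param method `"nearest"` or `"bilinear"`.
#' @param categorical Flag the layer categorical; bilinear is then refused.
#' @return An `fvc_grid` on the target geometry.
#' @export
align_resample <- function(grid, target, method = c("nearest", "bilinear"),
                           categorical = inherits(grid, "fvc_classified")) {
  method <- match.arg(method)
  if (categorical && method == "bilinear")
    stop("bilinear resampling is not allowed on a categorical layer")
  geom <- grid_geometry(target)
  src <- grid_geometry(grid)
  tc <- geom_cell_centers(geom)
  # fractional (row, col) position of each target center in source pixel space
  fc <- (tc$x - src$x0) / src$dx + 1
  fr <- (src$y0 - tc$y) / src$dy + 1
  if (max(fc) < 0.5 || min(fc) > src$ncols + 0.5 ||
      max(fr) < 0.5 || min(fr) > src$nrows + 0.5)
    stop("source and target geometries do not overlap spatially")
  nr <- geom$nrows; nc <- geom$ncols
  FR <- matrix(fr, nr, nc)              # varies by row
  FC <- matrix(fc, nr, nc, byrow = TRUE)
  v <- grid$values; v[grid$mask] <- NA_real_
  clampi <- function(i, n) pmin(pmax(i, 1L), n)
  if (method == "nearest") {
    ri <- clampi(as.integer(round(FR)), src$nrows)
    ci <- clampi(as.integer(round(FC)), src$ncols)
    out <- matrix(v[cbind(as.vector(ri), as.vector(ci))], nr, nc)
  } else {
    r0 <- clampi(floor(FR), src$nrows); r1 <- clampi(r0 + 1, src$nrows)
    c0 <- clampi(floor(FC), src$ncols); c1 <- clampi(c0 + 1, src$ncols)
    wr <- pmin(pmax(FR - floor(FR), 0), 1)
    wc <- pmin(pmax(FC - floor(FC), 0), 1)
    g <- function(ri, ci) matrix(v[cbind(as.vector(ri), as.vector(ci))], nr, nc)
    out <- (1 - wr) * ((1 - wc) * g(r0, c0) + wc * g(r0, c1)) +
      wr * ((1 - wc) * g(r1, c0) + wc * g(r1, c1))
  }
  res <- new_grid(out, list(x0 = geom$x0, y0 = geom$y0, dx = geom$dx, dy = geom$dy),
                  mask = !is.finite(out), units = grid$units, crs_tag = grid$crs_tag)
  if (inherits(grid, "fvc_classified")) {
    res$labels <- grid$labels
    class(res) <- c("fvc_classified", "fvc_grid")
  }
  res
}

# ---------------------------------------------------------------------------
# Inverse distance weighting
# ---------------------------------------------------------------------------

#' Interpolate scattered point samples onto a grid by inverse distance weighting
#'
#' Each cell takes the weighted mean of its `k_neighbors` nearest samples with
#' weights d^(-power); a cell coincident with a sample (distance below `eps`)
#' returns that sample's value exactly.
#'
#' @param samples Data frame with columns `x`, `y`, `value`.
#' @param target Target geometry (`fvc_grid` or [grid_geometry()] list).
#' @param power Positive distance-decay exponent (GIS default 2).
#' @param k_neighbors Number of nearest samples used per cell (default 12).
#' @param eps Coincidence tolerance in map units.
#' @return An `fvc_grid` on the target geometry.
#' @export
idw_interpolate <- function(samples, target, power = 2, k_neighbors = 12,
                            eps = 1e-9) {
  stopifnot(is.data.frame(samples), all(c("x", "y", "value") %in% names(samples)))
  if (nrow(samples) < 1) stop("at least one sample is required")
  if (!all(is.finite(as.matrix(samples[c("x", "y", "value")]))))
    stop("samples must have finite coordinates and values")
  if (power <= 0) stop("power must be positive")
  geom <- grid_geometry(target)
  cc <- geom_cell_centers(geom)
  X <- matrix(cc$x, geom$nrows, geom$ncols, byrow = TRUE)
  Y <- matrix(cc$y, geom$nrows, geom$ncols)
  k <- min(k_neighbors, nrow(samples))
  ncell <- length(X)
  # distance matrix cells x samples (sample counts are small in practice)
  D <- sqrt(outer(as.vector(X), samples$x, "-")^2 +
            outer(as.vector(Y), samples$y, "-")^2)
  out <- numeric(ncell)
  for (i in seq_len(ncell)) {
    d <- D[i, ]
    j <- which.min(d)
    if (d[j] < eps) { out[i] <- samples$value[j]; next }
    sel <- order(d)[seq_len(k)]
    w <- d[sel]^(-power)
    out[i] <- sum(w * samples$value[sel]) / sum(w)
  }
  new_grid(matrix(out, geom$nrows, geom$ncols),
           list(x0 = geom$x0, y0 = geom$y0, dx = geom$dx, dy = geom$dy))
}

# ---------------------------------------------------------------------------
# DEM derivatives (Horn 3x3)
# ---------------------------------------------------------------------------

#' Slope and aspect from a DEM (Horn's method)
#'
#' Third-order finite differences over the 3x3 neighbourhood. Slope is in
#' degrees in \[0, 90); aspect is the compass direction the surface faces
#' (degrees clockwise from north, in \[0, 360)); cells flatter than
#' `flat_threshold` get aspect -1, the conventional "flat" code. Border cells
#' and cells with any masked neighbour are masked.
#'
#' @param dem Elevation `fvc_grid`, projected, metric cell size.
#' @param flat_threshold Slope (degrees) below which aspect is coded -1.
#' @return List with `slope` and `aspect` grids.
#' @export
slope_aspect <- function(dem, flat_threshold = 0.5) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("DEM must be at least 3 x 3")
  z[dem$mask] <- NA_real_
  dx <- dem$transform$dx; dy <- dem$transform$dy
  # shifted views of the 3x3 window around interior cells
  sh <- function(dr, dc) z[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc)]
  a <- sh(-1, -1); b <- sh(-1, 0); cc_ <- sh(-1, 1)
  d <- sh(0, -1);                  f <- sh(0, 1)
  g <- sh(1, -1);  h <- sh(1, 0);  i <- sh(1, 1)
  dzdx <- ((cc_ + 2 * f + i) - (a + 2 * d + g)) / (8 * dx)   # east
  # dz/dy with y increasing northward: north row (a,b,c) minus south row (g,h,i)
  dzdy <- ((a + 2 * b + cc_) - (g + 2 * h + i)) / (8 * dy)
  slope_int <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  # aspect = compass bearing of the downhill (facing) direction
  asp_int <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  asp_int[slope_int < flat_threshold] <- -1
  slope <- matrix(NA_real_, nr, nc); aspect <- matrix(NA_real_, nr, nc)
  slope[2:(nr - 1), 2:(nc - 1)] <- slope_int
  aspect[2:(nr - 1), 2:(nc - 1)] <- asp_int
  msk <- !is.finite(slope)
  list(slope = new_grid(slope, dem$transform, msk, units = "degrees",
                        crs_tag = dem$crs_tag),
       aspect = new_grid(aspect, dem$transform, msk | !is.finite(aspect),
                         units = "degrees_from_north", crs_tag = dem$crs_tag))
}
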