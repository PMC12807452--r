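#' Cell perimeter geometry
#'
#' A simple (non-self-intersecting) closed polygon in pixel-unit coordinates,
#' vertex order with implicit closure. A duplicated closing vertex is dropped.
#'
#' @param x,y numeric vectors of vertex coordinates in pixel units.
#' @return an object of class `cell_geometry`: list with `x`, `y`,
#'   `area_px2`, `centroid` (x, y).
#' @export
cell_geometry <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (any(!is.finite(x)) || any(!is.finite(y)))
        stop("vertex coordinates must be finite")
    n <- length(x)
    if (n >= 4 && x[1] == x[n] && y[1] == y[n]) {  # drop explicit closure
        x <- x[-n]; y <- y[-n]; n <- n - 1L
    }
    if (n < 3L) stop("a polygon needs at least 3 distinct vertices")
    if (!polygon_is_simple(x, y))
        stop("polygon is self-intersecting (not simple)")
    a <- polygon_area(x, y)
    if (a <= 0) stop("polygon has zero area")
    structure(list(x = x, y = y, area_px2 = a,
                   centroid = polygon_centroid(x, y)),
              class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
    cat(sprintf("<cell_geometry> %d vertices, area %.1f px^2, centroid (%.1f, %.1f)\n",
                length(x$x), x$area_px2, x$centroid[1], x$centroid[2]))
    invisible(x)
}

# shoelace area (absolute)
polygon_area <- function(x, y) {
    n <- length(x)
    j <- c(2:n, 1)
    abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_centroid <- function(x, y) {
    n <- length(x)
    j <- c(2:n, 1)
    cr <- x * y[j] - x[j] * y
    a <- sum(cr) / 2
    c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

# proper-crossing test between all non-adjacent edge pairs; O(n^2), vertex
# counts here are small
polygon_is_simple <- function(x, y) {
    n <- length(x)
    seg <- cbind(x, y, x[c(2:n, 1)], y[c(2:n, 1)])
    ccw <- function(ax, ay, bx, by, cx, cy)
        (by - ay) * (cx - ax) - (bx - ax) * (cy - ay)
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            if (j == i + 1L || (i == 1L && j == n)) next  # adjacent edges
            d1 <- ccw(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
            d2 <- ccw(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
            d3 <- ccw(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
            d4 <- ccw(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
            if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
                ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(FALSE)
        }
    }
    TRUE
}

#' Read a cell perimeter from a two-column CSV
#'
#' Accepts an optional header row; coordinates are pixel units. The polygon
#' is validated simple and a duplicated closing vertex is dropped.
#'
#' @param path CSV path with two numeric columns (x, y).
#' @return a [cell_geometry()].
#' @export
read_perimeter <- function(path) {
    first <- readLines(path, n = 1L)
    has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
    d <- utils::read.csv(path, header = has_header)
    if (ncol(d) < 2L) stop("perimeter CSV needs two columns")
    cell_geometry(as.numeric(d[[1]]), as.numeric(d[[2]]))
}

#' Write a cell perimeter as a two-column CSV
#' @param geom a [cell_geometry()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_perimeter <- function(geom, path) {
    stopifnot(inherits(geom, "cell_geometry"))
    utils::write.csv(data.frame(x = geom$x, y = geom$y), path, row.names = FALSE)
    invisible(path)
}

#' Are points inside a polygon?
#' @param geom a [cell_geometry()].
#' @param px,py point coordinates in pixel units.
#' @return logical vector (boundary counts as inside).
#' @export
points_in_cell <- function(geom, px, py) {
    pracma::inpolygon(px, py, geom$x, geom$y, boundary = TRUE)
}

#' Distance from points to the polygon boundary
#' @param geom a [cell_geometry()].
#' @param px,py point coordinates in pixel units.
#' @return numeric distances in pixel units (unsigned).
#' @export
distance_to_perimeter <- function(geom, px, py) {
    dist_to_polygon_cpp(px, py, geom$x, geom$y)
}

#' Rasterize a polygon interior to a mask
#'
#' A pixel is interior when its centre lies inside (or on) the polygon.
#'
#' @param geom a [cell_geometry()].
#' @param dim integer (nrow, ncol) of the target grid; default tight to the
#'   polygon extent.
#' @param pixel_size_nm pixel size for the resulting mask.
#' @return a [binary_mask()] of the interior.
#' @export
rasterize_polygon <- function(geom, dim = NULL, pixel_size_nm) {
    if (is.null(dim)) dim <- c(ceiling(max(geom$y)) + 1L, ceiling(max(geom$x)) + 1L)
    nr <- dim[1]; nc <- dim[2]
    xs <- rep(seq_len(nc) - 0.5, each = nr)
    ys <- rep(seq_len(nr) - 0.5, times = nc)
    inside <- points_in_cell(geom, xs, ys)
    binary_mask(matrix(as.integer(inside), nr, nc), pixel_size_nm)
}

#' Cell area in square micrometres
#' @param geom a [cell_geometry()].
#' @param pixel_size_nm pixel size in nm.
#' @return scalar area in um^2.
#' @export
cell_area_um2 <- function(geom, pixel_size_nm) {
    geom$area_px2 * (pixel_size_nm / 1000)^2
}
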