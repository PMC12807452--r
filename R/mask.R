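#' Binary raster mask with a physical pixel size
#'
#' The universal raster currency of the package: a 2D matrix of 0/1 with the
#' edge length of one pixel in nanometres. Any nonzero input value is coerced
#' to foreground.
#'
#' @param px numeric or logical matrix; nonzero/`TRUE` means foreground.
#' @param pixel_size_nm positive scalar, edge length of one pixel in nm.
#' @return an object of class `binary_mask`: a list with `px` (integer 0/1
#'   matrix) and `pixel_size_nm`.
#' @export
binary_mask <- function(px, pixel_size_nm) {
    if (!is.matrix(px)) stop("`px` must be a matrix, got ", class(px)[1])
    if (length(px) == 0L) stop("mask grid must be non-empty")
    if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
        !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
        stop("`pixel_size_nm` must be a single positive number")
    m <- matrix(as.integer(px != 0), nrow(px), ncol(px))
    structure(list(px = m, pixel_size_nm = as.numeric(pixel_size_nm)),
              class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
    cat(sprintf("<binary_mask> %d x %d px @ %g nm/px, %d foreground px (%.2f%%)\n",
                nrow(x$px), ncol(x$px), x$pixel_size_nm, sum(x$px),
                100 * mean(x$px)))
    invisible(x)
}

is_binary_mask <- function(x) inherits(x, "binary_mask")

#' Foreground fraction of a mask
#' @param mask a [binary_mask()].
#' @return scalar in \[0, 1\].
#' @export
foreground_fraction <- function(mask) {
    stopifnot(is_binary_mask(mask))
    mean(mask$px)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a mask as an 8-bit single-channel TIFF with a JSON sidecar
#'
#' Foreground is written as 255, background as 0. The pixel size is recorded
#' in a sidecar `<path-without-ext>.json` as `{"pixel_size_nm": ...}` rather
#' than in TIFF tags.
#'
#' @param mask a [binary_mask()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
    stopifnot(is_binary_mask(mask))
    tiff::writeTIFF(matrix(as.numeric(mask$px), nrow(mask$px), ncol(mask$px)),
                    path, bits.per.sample = 8L, compression = "none")
    jsonlite::write_json(list(pixel_size_nm = mask$pixel_size_nm),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a single-channel TIFF as a binary mask
#'
#' Any nonzero pixel is foreground. The pixel size comes from the explicit
#' argument if given, otherwise from the JSON sidecar written by
#' [write_mask()].
#'
#' @param path TIFF path.
#' @param pixel_size_nm optional pixel size override in nm.
#' @return a [binary_mask()].
#' @export
read_mask <- function(path, pixel_size_nm = NULL) {
    img <- tiff::readTIFF(path, all = FALSE)
    if (!is.matrix(img))
        stop("expected a single-channel 2D TIFF, got array of shape ",
             paste(dim(img), collapse = " x "))
    if (is.null(pixel_size_nm)) {
        sp <- sidecar_path(path)
        if (!file.exists(sp))
            stop("no `pixel_size_nm` given and no sidecar found at ", sp)
        pixel_size_nm <- jsonlite::read_json(sp)$pixel_size_nm
    }
    binary_mask(img, pixel_size_nm)
}

#' Render a localization table to a binary map
#'
#' Bins point localizations (nm coordinates) onto a raster: every pixel that
#' contains at least one localization becomes foreground. Pixel index is
#' `floor(coord_nm / pixel_size_nm)` (0-based), i.e. matrix cell
#' `[floor(y/px) + 1, floor(x/px) + 1]`. The grid is tight to the data extent
#' plus `margin_px` pixels on every side; with the default margin of 0 a
#' localization at (12 nm, 12 nm) on a 5 nm grid lands in 0-based pixel
#' (2, 2).
#'
#' @param x_nm,y_nm numeric vectors of localization coordinates in nm
#'   (non-negative).
#' @param pixel_size_nm rendering pixel size in nm (default 5).
#' @param margin_px non-negative integer padding added on all sides.
#' @return a [binary_mask()]; attribute `offset_px` gives the (row, col)
#'   0-based offset of the original origin within the padded grid.
#' @export
render_localizations <- function(x_nm, y_nm, pixel_size_nm = 5, margin_px = 0L) {
    if (length(x_nm) == 0L) stop("empty localization table: no extent to render")
    if (length(x_nm) != length(y_nm)) stop("x and y must have equal length")
    if (any(!is.finite(x_nm)) || any(!is.finite(y_nm)))
        stop("localization coordinates must be finite")
    if (any(x_nm < 0) || any(y_nm < 0))
        stop("localization coordinates must be non-negative")
    col <- floor(x_nm / pixel_size_nm) + 1L + margin_px
    row <- floor(y_nm / pixel_size_nm) + 1L + margin_px
    nr <- max(row) + margin_px
    nc <- max(col) + margin_px
    m <- matrix(0L, nr, nc)
    m[cbind(row, col)] <- 1L
    out <- binary_mask(m, pixel_size_nm)
    attr(out, "offset_px") <- c(margin_px, margin_px)
    out
}

# internal: elementwise AND of two masks on the same grid
mask_and <- function(a, b) {
    check_same_grid(a, b)
    binary_mask(a$px * b$px, a$pixel_size_nm)
}

check_same_grid <- function(a, b) {
    if (!identical(dim(a$px), dim(b$px)))
        stop("grid mismatch: ", paste(dim(a$px), collapse = "x"), " vs ",
             paste(dim(b$px), collapse = "x"))
    if (!isTRUE(all.equal(a$pixel_size_nm, b$pixel_size_nm)))
        stop("pixel size mismatch: ", a$pixel_size_nm, " vs ", b$pixel_size_nm)
    invisible(TRUE)
}

#' Euclidean distance map to a mask's foreground
#'
#' For every pixel, the exact centre-to-centre Euclidean distance (in pixels)
#' to the nearest foreground pixel; 0 on the foreground itself, `Inf` if the
#' mask is empty.
#'
#' @param mask a [binary_mask()].
#' @return numeric matrix of distances in pixel units.
#' @export
distance_map <- function(mask) {
    stopifnot(is_binary_mask(mask))
    d2 <- edt_sq_cpp(mask$px)
    d <- sqrt(d2)
    d[d2 >= 1e15] <- Inf
    d
}

#' Morphological dilation of a mask by a Euclidean disk
#'
#' A pixel belongs to the dilated mask when its centre lies within
#' `radius_px` of some foreground pixel centre. Implemented via the exact
#' Euclidean distance transform, so dilation is consistent with
#' [nearest_distances()] by construction.
#'
#' @param mask a [binary_mask()].
#' @param radius_px dilation radius in pixels (may be fractional).
#' @return a [binary_mask()].
#' @export
dilate_mask <- function(mask, radius_px) {
    stopifnot(is_binary_mask(mask), radius_px >= 0)
    binary_mask(distance_map(mask) <= radius_px, mask$pixel_size_nm)
}
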