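#' Labeled particle set
#'
#' Connected pixel footprints with per-particle centroids and physical areas.
#' `area_nm2` is always the pixel-footprint area (`n_px * pixel_size_nm^2`),
#' so the set-level invariant `sum(n_px) * pixel_area == sum(area_nm2)` holds
#' exactly.
#'
#' @param labels integer matrix; 0 = background, k = footprint of particle k.
#'   Labels need not be contiguous; empty labels are dropped.
#' @param pixel_size_nm pixel size in nm.
#' @param cell_area_um2 optional cell area in um^2 used for densities.
#' @return an object of class `particle_set`: list with `labels`, `table`
#'   (data.frame: id, n_px, cx_px, cy_px, area_nm2), `pixel_size_nm`,
#'   `cell_area_um2`.
#' @export
particle_set <- function(labels, pixel_size_nm, cell_area_um2 = NA_real_) {
    stopifnot(is.matrix(labels))
    idx <- which(labels > 0L)
    px_area <- pixel_size_nm^2
    if (length(idx) == 0L) {
        tab <- data.frame(id = integer(), n_px = integer(),
                          cx_px = numeric(), cy_px = numeric(),
                          area_nm2 = numeric())
    } else {
        lab <- labels[idx]
        row <- ((idx - 1L) %% nrow(labels)) + 1L
        col <- ((idx - 1L) %/% nrow(labels)) + 1L
        ids <- sort(unique(lab))
        n_px <- as.integer(tapply(rep(1L, length(lab)), lab, sum)[as.character(ids)])
        cx <- as.numeric(tapply(col - 0.5, lab, mean)[as.character(ids)])
        cy <- as.numeric(tapply(row - 0.5, lab, mean)[as.character(ids)])
        tab <- data.frame(id = ids, n_px = n_px, cx_px = cx, cy_px = cy,
                          area_nm2 = n_px * px_area)
        rownames(tab) <- NULL
    }
    structure(list(labels = labels, table = tab,
                   pixel_size_nm = as.numeric(pixel_size_nm),
                   cell_area_um2 = cell_area_um2),
              class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
    cat(sprintf("<particle_set> %d particles @ %g nm/px", nrow(x$table),
                x$pixel_size_nm))
    if (nrow(x$table) > 0)
        cat(sprintf(", median area %.0f nm^2", median(x$table$area_nm2)))
    cat("\n")
    invisible(x)
}

is_particle_set <- function(x) inherits(x, "particle_set")

n_particles <- function(ps) nrow(ps$table)

#' Label connected particles in a binary mask
#'
#' Maximal connected components under 4- or 8-connectivity, labeled
#' deterministically in scan order.
#'
#' @param mask a [binary_mask()].
#' @param connectivity 4 or 8 (default 8, the common particle-analysis
#'   convention).
#' @param cell_area_um2 optional cell area for density reporting.
#' @return a [particle_set()].
#' @export
label_particles <- function(mask, connectivity = 8L, cell_area_um2 = NA_real_) {
    stopifnot(is_binary_mask(mask))
    labels <- cc_label_cpp(mask$px, as.integer(connectivity))
    particle_set(labels, mask$pixel_size_nm, cell_area_um2)
}

#' Rasterize a particle set back to a binary mask
#'
#' The foreground is the union of all footprints. The attribute
#' `n_components` records the number of connected components of that union
#' (8-connectivity); when particles are disjoint and non-adjacent it equals
#' the particle count.
#'
#' @param ps a [particle_set()].
#' @return a [binary_mask()].
#' @export
rasterize <- function(ps) {
    stopifnot(is_particle_set(ps))
    out <- binary_mask(ps$labels > 0L, ps$pixel_size_nm)
    attr(out, "n_components") <- max(cc_label_cpp(out$px, 8L), 0L)
    out
}

#' Draw circular particles onto a raster
#'
#' Paints filled disks of the requested physical areas (radius
#' `sqrt(area/pi)`) at the given centres. A pixel belongs to a disk when its
#' centre is within the radius. Later circles overwrite earlier ones where
#' footprints overlap; the per-particle `area_nm2` in the result is the
#' realized (painted) pixel area, which differs from the requested area only
#' by rasterization.
#'
#' @param cx_px,cy_px circle centres in pixel units.
#' @param area_nm2 requested circle areas in nm^2.
#' @param dim integer (nrow, ncol) of the grid.
#' @param pixel_size_nm pixel size in nm.
#' @param cell_area_um2 optional cell area for density reporting.
#' @return a [particle_set()] (particles whose footprint was entirely
#'   overwritten are absent).
#' @export
draw_circles <- function(cx_px, cy_px, area_nm2, dim, pixel_size_nm,
                         cell_area_um2 = NA_real_) {
    r_px <- sqrt(area_nm2 / pi) / pixel_size_nm
    labels <- paint_disks_cpp(as.integer(dim[1]), as.integer(dim[2]),
                              cx_px, cy_px, r_px)
    particle_set(labels, pixel_size_nm, cell_area_um2)
}

#' Threshold a grayscale image to a binary mask
#'
#' Optional background subtraction by grayscale morphological opening with a
#' disc (flat-kernel rolling-ball analogue), then a fixed or Otsu threshold.
#' The threshold actually applied is recorded in the `threshold` attribute.
#'
#' @param img numeric matrix (grayscale).
#' @param pixel_size_nm pixel size in nm.
#' @param method "fixed" or "otsu".
#' @param threshold threshold value for `method = "fixed"`; pixels strictly
#'   above it become foreground.
#' @param background "none" or "opening" (subtract the grayscale opening).
#' @param radius_px disc radius in pixels for background estimation
#'   (default 50).
#' @return a [binary_mask()] with attribute `threshold`.
#' @export
binarize <- function(img, pixel_size_nm,
                     method = c("fixed", "otsu"), threshold = NULL,
                     background = c("none", "opening"), radius_px = 50L) {
    method <- match.arg(method)
    background <- match.arg(background)
    if (!is.matrix(img) || !is.numeric(img)) stop("`img` must be a numeric 2D matrix")
    if (background == "opening") {
        brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
        bg <- EBImage::opening(img, brush)
        img <- pmax(img - bg, 0)
    }
    if (method == "fixed") {
        if (is.null(threshold)) stop("`threshold` is required for method = \"fixed\"")
        thr <- threshold
    } else {
        rng <- range(img)
        if (rng[1] == rng[2]) stop("Otsu threshold undefined on a constant image")
        scaled <- (img - rng[1]) / (rng[2] - rng[1])
        thr <- EBImage::otsu(scaled, range = c(0, 1)) * (rng[2] - rng[1]) + rng[1]
    }
    out <- binary_mask(img > thr, pixel_size_nm)
    attr(out, "threshold") <- thr
    out
}

#' Filter particles by minimum area
#'
#' Keeps particles with `area_nm2 >= min_area_nm2` ("smaller than" are
#' excluded, so a particle exactly at the limit is kept). Particle ids and
#' order are stable; the operation is idempotent and monotone.
#'
#' @param ps a [particle_set()].
#' @param min_area_nm2 non-negative area threshold in nm^2 (the super-
#'   resolution analyses here conventionally use 400 nm^2, the imaging
#'   resolution limit).
#' @return a filtered [particle_set()].
#' @export
filter_by_area <- function(ps, min_area_nm2) {
    stopifnot(is_particle_set(ps), min_area_nm2 >= 0)
    keep <- ps$table$area_nm2 >= min_area_nm2
    labels <- ps$labels
    if (any(!keep)) labels[labels %in% ps$table$id[!keep]] <- 0L
    out <- ps
    out$labels <- labels
    out$table <- ps$table[keep, , drop = FALSE]
    rownames(out$table) <- NULL
    out
}

#' Descriptive particle statistics
#'
#' Densities per 10 and per 100 um^2, the median footprint area, and the
#' cumulative area distribution. The median uses lower interpolation: on even
#' n it is the lower of the two middle order statistics.
#'
#' @param ps a [particle_set()].
#' @param cell_area_um2 cell area in um^2; defaults to the value stored in
#'   `ps`.
#' @return list with `n`, `density_per_10um2`, `density_per_100um2`,
#'   `median_area_nm2` (`NA` for an empty set), and `cumulative`
#'   (data.frame: area_nm2, frac).
#' @export
particle_stats <- function(ps, cell_area_um2 = ps$cell_area_um2) {
    stopifnot(is_particle_set(ps))
    if (is.na(cell_area_um2) || cell_area_um2 <= 0)
        stop("`cell_area_um2` must be a positive number")
    n <- n_particles(ps)
    areas <- sort(ps$table$area_nm2)
    med <- if (n == 0L) NA_real_ else areas[floor((n + 1) / 2)]
    cumulative <- if (n == 0L) data.frame(area_nm2 = numeric(), frac = numeric())
                  else data.frame(area_nm2 = areas, frac = seq_len(n) / n)
    list(n = n,
         density_per_10um2 = n / cell_area_um2 * 10,
         density_per_100um2 = n / cell_area_um2 * 100,
         median_area_nm2 = med,
         cumulative = cumulative)
}

#' Per-cell abundance correlation between two channels
#'
#' Ordinary least squares of counts of channel B on counts of channel A
#' across cells.
#'
#' @param counts_a,counts_b equal-length numeric vectors (>= 3 cells).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
abundance_correlation <- function(counts_a, counts_b) {
    if (length(counts_a) != length(counts_b))
        stop("count vectors must have equal length")
    if (length(counts_a) < 3L) stop("need at least 3 cells")
    if (stats::var(counts_a) == 0) stop("channel A counts have zero variance")
    fit <- stats::lm(counts_b ~ counts_a)
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((counts_b - mean(counts_b))^2)
    list(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot)
}
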