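as_mask <- function(x) {
    if (is_binary_mask(x)) return(x)
    if (is_particle_set(x)) return(binary_mask(x$labels > 0L, x$pixel_size_nm))
    stop("expected a binary_mask or particle_set, got ", class(x)[1])
}

as_pset <- function(x, connectivity = 8L) {
    if (is_particle_set(x)) return(x)
    if (is_binary_mask(x)) return(label_particles(x, connectivity))
    stop("expected a binary_mask or particle_set, got ", class(x)[1])
}

#' Binary overlap colocalization between two channels
#'
#' The overlap mask is the pixelwise product of the two binary channels.
#' Object-level colocalization counts a particle as colocalized when at
#' least one of its pixels lies in the overlap; area-level colocalization is
#' overlap pixels over the foreground pixels of the denominator channel.
#' Both directions are always reported, because "X colocalizes with Y by p%"
#' depends on which channel is the denominator.
#'
#' @param A,B [binary_mask()] or [particle_set()] on the same grid. When a
#'   mask is given, particles are its 8-connected components.
#' @return object of class `coloc_result`: list with `n_A`, `n_B`,
#'   `object_pct_A_to_B`, `object_pct_B_to_A`, `area_pct_A_to_B`,
#'   `area_pct_B_to_A`, `denominator` ("first-named channel of each
#'   direction").
#' @export
overlap_coloc <- function(A, B) {
    psA <- as_pset(A); psB <- as_pset(B)
    mA <- as_mask(psA); mB <- as_mask(psB)
    check_same_grid(mA, mB)
    ov <- mA$px * mB$px
    obj_pct <- function(ps) {
        n <- n_particles(ps)
        if (n == 0L) return(NA_real_)
        hit <- unique(ps$labels[ov == 1L & ps$labels > 0L])
        100 * length(hit) / n
    }
    area_pct <- function(m) {
        fg <- sum(m$px)
        if (fg == 0L) NA_real_ else 100 * sum(ov) / fg
    }
    structure(list(n_A = n_particles(psA), n_B = n_particles(psB),
                   object_pct_A_to_B = obj_pct(psA),
                   object_pct_B_to_A = obj_pct(psB),
                   area_pct_A_to_B = area_pct(mA),
                   area_pct_B_to_A = area_pct(mB),
                   denominator = "first-named channel of each direction"),
              class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
    cat(sprintf(paste0("<coloc_result> n_A = %d, n_B = %d\n",
                       "  object: A->B %.1f%%, B->A %.1f%%\n",
                       "  area:   A->B %.1f%%, B->A %.1f%%\n"),
                x$n_A, x$n_B, x$object_pct_A_to_B, x$object_pct_B_to_A,
                x$area_pct_A_to_B, x$area_pct_B_to_A))
    invisible(x)
}

#' Classify puncta against a compartment mask
#'
#' Assigns each particle to inside/outside the compartment either by its
#' centroid pixel (default; unambiguous for puncta small relative to the
#' compartment) or by any footprint pixel.
#'
#' @param puncta a [particle_set()].
#' @param compartment a [binary_mask()] on the same grid.
#' @param mode "centroid" or "any-pixel".
#' @return list with `n_inside`, `n_outside`, `pct_inside` (`NA` for an
#'   empty puncta set).
#' @export
classify_by_mask <- function(puncta, compartment,
                             mode = c("centroid", "any-pixel")) {
    mode <- match.arg(mode)
    stopifnot(is_particle_set(puncta), is_binary_mask(compartment))
    check_same_grid(as_mask(puncta), compartment)
    n <- n_particles(puncta)
    if (n == 0L)
        return(list(n_inside = 0L, n_outside = 0L, pct_inside = NA_real_))
    if (mode == "centroid") {
        col <- pmin(floor(puncta$table$cx_px) + 1L, ncol(compartment$px))
        row <- pmin(floor(puncta$table$cy_px) + 1L, nrow(compartment$px))
        inside <- compartment$px[cbind(row, col)] == 1L
    } else {
        hit <- unique(puncta$labels[compartment$px == 1L & puncta$labels > 0L])
        inside <- puncta$table$id %in% hit
    }
    list(n_inside = sum(inside), n_outside = sum(!inside),
         pct_inside = 100 * mean(inside))
}

#' Nearest distance from each A particle to channel B
#'
#' For every particle of A, the minimum distance to channel B under the
#' stated metric, in nm. The edge metric is the minimum centre-to-centre
#' distance between any A footprint pixel and any B foreground pixel (0 when
#' footprints overlap), computed by sampling the exact Euclidean distance
#' transform of B at A's footprint; it equals the brute-force all-pairs
#' minimum by construction.
#'
#' @param A a [particle_set()] (or mask, labeled at 8-connectivity).
#' @param B a [particle_set()] or [binary_mask()] on the same grid;
#'   must be non-empty.
#' @param metric "edge" or "centroid".
#' @return numeric vector of distances in nm, one per A particle (ordered as
#'   `A$table`).
#' @export
nearest_distances <- function(A, B, metric = c("edge", "centroid")) {
    metric <- match.arg(metric)
    psA <- as_pset(A)
    if (metric == "edge") {
        mB <- as_mask(B)
        check_same_grid(as_mask(psA), mB)
        if (sum(mB$px) == 0L) stop("channel B is empty")
        d <- distance_map(mB)
        idx <- which(psA$labels > 0L)
        mins <- tapply(d[idx], psA$labels[idx], min)
        as.numeric(mins[as.character(psA$table$id)]) * psA$pixel_size_nm
    } else {
        psB <- as_pset(B)
        if (n_particles(psB) == 0L) stop("channel B is empty")
        ax <- psA$table$cx_px; ay <- psA$table$cy_px
        bx <- psB$table$cx_px; by <- psB$table$cy_px
        vapply(seq_along(ax), function(i)
            sqrt(min((ax[i] - bx)^2 + (ay[i] - by)^2)), numeric(1)) *
            psA$pixel_size_nm
    }
}

#' Fraction of A particles within a distance of channel B
#'
#' The empirical CDF of [nearest_distances()] evaluated at `d_nm`, times
#' 100. With the edge metric this equals the dilation-based count (dilate B
#' by `d_nm`, count A particles touching the dilated mask) exactly, since
#' both derive from the same distance transform.
#'
#' @inheritParams nearest_distances
#' @param d_nm distance threshold in nm.
#' @return percentage in \[0, 100\].
#' @export
fraction_within <- function(A, B, d_nm, metric = c("edge", "centroid")) {
    100 * mean(nearest_distances(A, B, metric) <= d_nm)
}

#' Cumulative dilation ("ring") localization-preference profile
#'
#' Progressively dilates channel A's mask by Euclidean disks of the given
#' radii and multiplies each dilation with channel B, recording the fraction
#' of B foreground captured (cumulative occupancy). The normalized profile
#' divides by the value at the largest radius, so its final value is exactly
#' 1 whenever that value is nonzero. The canonical radius ladder is 20, 40,
#' 60, 80, 100 and 200 nm with the 200 nm value as the normalization
#' reference.
#'
#' @param A a [particle_set()] or [binary_mask()] (the channel being
#'   dilated).
#' @param B a [binary_mask()] (or particle set) whose occupancy is measured.
#' @param radii_nm strictly increasing dilation radii in nm.
#' @return object of class `ring_profile`: data.frame with `radius_nm`,
#'   `radius_px` (rounded to whole pixels; residual in attribute
#'   `residual_px`), `raw` (cumulative occupancy of B, in \[0, 1\]), and
#'   `normalized` (`NA` when the raw value at the maximum radius is 0).
#' @export
ring_profile <- function(A, B, radii_nm = c(20, 40, 60, 80, 100, 200)) {
    if (any(diff(radii_nm) <= 0)) stop("radii_nm must be strictly increasing")
    mA <- as_mask(A); mB <- as_mask(B)
    check_same_grid(mA, mB)
    if (sum(mA$px) == 0L) stop("channel A is empty")
    px <- mA$pixel_size_nm
    r_px <- round(radii_nm / px)
    residual <- radii_nm / px - r_px
    total_B <- sum(mB$px)
    d <- distance_map(mA)
    raw <- vapply(r_px, function(r)
        if (total_B == 0L) 0 else sum(mB$px[d <= r]) / total_B, numeric(1))
    normalized <- if (raw[length(raw)] > 0) raw / raw[length(raw)]
                  else rep(NA_real_, length(raw))
    out <- data.frame(radius_nm = radii_nm, radius_px = r_px,
                      raw = raw, normalized = normalized)
    class(out) <- c("ring_profile", "data.frame")
    attr(out, "residual_px") <- residual
    out
}

#' Per-annulus occupancy from a cumulative ring profile
#'
#' Successive differences of the cumulative occupancy: the fraction of
#' channel-B signal falling in each concentric annulus (the first entry is
#' the occupancy up to the first radius). Non-negative by monotonicity, and
#' the annuli sum back to the final cumulative value.
#'
#' @param rp a [ring_profile()].
#' @return data.frame with `radius_nm` (outer radius of each annulus) and
#'   `annulus` occupancy.
#' @export
annulus_profile <- function(rp) {
    stopifnot(inherits(rp, "ring_profile"))
    data.frame(radius_nm = rp$radius_nm,
               annulus = c(rp$raw[1], diff(rp$raw)))
}
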