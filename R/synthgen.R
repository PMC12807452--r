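#' Simulation configuration for coupled two-channel particle fields
#'
#' Houses the generative knobs of the synthetic scenes: particle densities
#' (per 100 um^2, the reporting unit used for transcript and cluster
#' densities), the coupling fraction `f` of channel-B particles placed near a
#' channel-A particle, the coupling distance `delta` (edge-to-edge, nm), and
#' lognormal particle-area parameters per channel.
#'
#' @param pixel_size_nm pixel size in nm (> 0).
#' @param density_A,density_B particles per 100 um^2 (>= 0).
#' @param coupling_fraction fraction `f` in \[0, 1\] of B particles placed by
#'   the coupling rule.
#' @param coupling_distance_nm coupling distance `delta` >= 0 (edge-to-edge).
#' @param area_median_nm2 lognormal median footprint area in nm^2; length 1
#'   (both channels) or 2 (A, B).
#' @param area_sigma lognormal sigma (sdlog); length 1 or 2.
#' @param n_A,n_B optional fixed particle counts overriding the Poisson draw.
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(pixel_size_nm = 5, density_A = 50, density_B = 50,
                       coupling_fraction = 0, coupling_distance_nm = 0,
                       area_median_nm2 = c(1691, 975), area_sigma = 0.5,
                       n_A = NULL, n_B = NULL, seed = 1L) {
    if (pixel_size_nm <= 0) stop("pixel_size_nm must be positive")
    if (density_A < 0 || density_B < 0) stop("densities must be non-negative")
    if (coupling_fraction < 0 || coupling_fraction > 1)
        stop("coupling_fraction must be in [0, 1]")
    if (coupling_distance_nm < 0) stop("coupling_distance_nm must be non-negative")
    rec2 <- function(v) if (length(v) == 1L) c(v, v) else v[1:2]
    structure(list(pixel_size_nm = pixel_size_nm,
                   density_A = density_A, density_B = density_B,
                   coupling_fraction = coupling_fraction,
                   coupling_distance_nm = coupling_distance_nm,
                   area_median_nm2 = rec2(area_median_nm2),
                   area_sigma = rec2(area_sigma),
                   n_A = n_A, n_B = n_B, seed = as.integer(seed)),
              class = "sim_config")
}

#' Generate an irregular polygonal cell perimeter
#'
#' Vertices sit at equally spaced base angles with radial (and slight
#' angular) jitter scaled by `irregularity`; angles stay strictly monotone so
#' the polygon is star-shaped about its centre and therefore simple. A
#' simplicity check with regeneration guards the construction anyway.
#'
#' @param seed integer RNG seed.
#' @param radius_px mean radius in pixels (>= 10).
#' @param irregularity jitter amount in \[0, 1).
#' @param n_vertices number of perimeter vertices (default 24).
#' @param center (x, y) centre in pixel units; default places the cell with a
#'   margin so the suggested grid (attribute `grid_dim`) contains it.
#' @return a [cell_geometry()] with attribute `grid_dim` = (nrow, ncol).
#' @export
make_cell_geometry <- function(seed, radius_px, irregularity = 0.15,
                               n_vertices = 24L, center = NULL) {
    if (radius_px < 10) stop("radius_px must be at least 10")
    if (irregularity < 0 || irregularity >= 1)
        stop("irregularity must be in [0, 1)")
    if (is.null(center)) center <- c(1.3 * radius_px, 1.3 * radius_px)
    set.seed(seed)
    base <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
    geom <- NULL
    for (attempt in 1:20) {
        th <- base + irregularity * runif(n_vertices, -0.3, 0.3) * (2 * pi / n_vertices)
        rr <- radius_px * (1 + irregularity * runif(n_vertices, -0.5, 0.5))
        g <- tryCatch(cell_geometry(center[1] + rr * cos(th),
                                    center[2] + rr * sin(th)),
                      error = function(e) NULL)
        if (!is.null(g)) { geom <- g; break }
    }
    if (is.null(geom)) stop("failed to generate a simple polygon after 20 attempts")
    attr(geom, "grid_dim") <- c(ceiling(2.6 * radius_px), ceiling(2.6 * radius_px))
    geom
}

geom_grid_dim <- function(geom, dim = NULL) {
    if (!is.null(dim)) return(as.integer(dim))
    gd <- attr(geom, "grid_dim")
    if (is.null(gd)) gd <- c(ceiling(max(geom$y)) + 2L, ceiling(max(geom$x)) + 2L)
    as.integer(gd)
}

# uniform points in the polygon with footprint clearance r_px from the
# boundary; batch rejection sampling
sample_in_polygon <- function(geom, n, r_px = 0, max_attempts = 1000L) {
    if (n == 0L) return(cbind(x = numeric(), y = numeric()))
    bx <- range(geom$x); by <- range(geom$y)
    out <- matrix(NA_real_, n, 2)
    got <- 0L
    for (i in seq_len(max_attempts)) {
        m <- max(2L * (n - got), 64L)
        px <- runif(m, bx[1], bx[2]); py <- runif(m, by[1], by[2])
        ok <- points_in_cell(geom, px, py)
        if (any(r_px > 0))
            ok <- ok & distance_to_perimeter(geom, px, py) >= max(r_px)
        k <- which(ok)
        if (length(k) > 0) {
            take <- k[seq_len(min(length(k), n - got))]
            out[(got + 1L):(got + length(take)), ] <- cbind(px[take], py[take])
            got <- got + length(take)
        }
        if (got == n) break
    }
    if (got < n)
        stop("could not place ", n, " points inside the polygon (clearance ",
             max(r_px), " px) after ", max_attempts, " rejection rounds")
    colnames(out) <- c("x", "y")
    out
}

# per-particle placement with individual clearance; loop over particles
sample_in_polygon_each <- function(geom, r_px, max_attempts = 1000L) {
    n <- length(r_px)
    out <- matrix(NA_real_, n, 2)
    bx <- range(geom$x); by <- range(geom$y)
    for (k in seq_len(n)) {
        placed <- FALSE
        for (a in seq_len(max_attempts)) {
            px <- runif(1, bx[1], bx[2]); py <- runif(1, by[1], by[2])
            if (points_in_cell(geom, px, py) &&
                distance_to_perimeter(geom, px, py) >= r_px[k]) {
                out[k, ] <- c(px, py); placed <- TRUE; break
            }
        }
        if (!placed)
            stop("failed to place particle ", k, " (radius ", round(r_px[k], 2),
                 " px) inside the cell after ", max_attempts, " attempts")
    }
    colnames(out) <- c("x", "y")
    out
}

#' Simulate a coupled two-channel particle field
#'
#' Channel-A particles are uniform in the cell interior with a Poisson count
#' at the configured density (or a fixed count override). Each channel-B
#' particle is, with probability `f`, "coupled": its centre is placed
#' uniformly in the disk of radius `r_A + delta` (pixel units) around a
#' uniformly chosen A particle, which guarantees an edge-to-edge distance of
#' at most `delta`; otherwise it is uniform in the interior. Footprints are
#' rasterized circles with lognormal target areas; whole footprints stay
#' inside the perimeter (rejection-sampled, capped attempts).
#'
#' @param geom a [cell_geometry()] (pixel units on the simulation grid).
#' @param cfg a [sim_config()].
#' @param dim optional grid (nrow, ncol); defaults to the geometry's
#'   suggested grid.
#' @return list with `A` and `B` ([particle_set()]s on the common grid) and
#'   `ground_truth` (data.frame: particle_id, channel, cx_px, cy_px,
#'   target_area_nm2, radius_px, coupled, partner).
#' @export
simulate_coupled_particles <- function(geom, cfg, dim = NULL) {
    stopifnot(inherits(geom, "cell_geometry"), inherits(cfg, "sim_config"))
    px <- cfg$pixel_size_nm
    dim <- geom_grid_dim(geom, dim)
    area_um2 <- cell_area_um2(geom, px)
    set.seed(cfg$seed)

    exp_A <- cfg$density_A * area_um2 / 100
    exp_B <- cfg$density_B * area_um2 / 100
    if (is.null(cfg$n_A) && cfg$density_A > 0 && exp_A < 1)
        stop("expected A count below 1 (", round(exp_A, 3), "); enlarge the cell or density")
    if (is.null(cfg$n_B) && cfg$density_B > 0 && exp_B < 1)
        stop("expected B count below 1 (", round(exp_B, 3), "); enlarge the cell or density")

    n_A <- if (!is.null(cfg$n_A)) cfg$n_A else rpois(1, exp_A)
    n_B <- if (!is.null(cfg$n_B)) cfg$n_B else rpois(1, exp_B)

    draw_areas <- function(n, ch) rlnorm(n, log(cfg$area_median_nm2[ch]),
                                         cfg$area_sigma[ch])
    area_A <- draw_areas(n_A, 1L); r_A <- sqrt(area_A / pi) / px
    area_B <- draw_areas(n_B, 2L); r_B <- sqrt(area_B / pi) / px

    pos_A <- sample_in_polygon_each(geom, r_A)

    coupled <- if (n_B > 0) rbinom(n_B, 1L, cfg$coupling_fraction) == 1L else logical(0)
    if (any(coupled) && n_A == 0L)
        stop("coupling requested but channel A is empty")
    delta_px <- cfg$coupling_distance_nm / px

    pos_B <- matrix(NA_real_, n_B, 2)
    partner <- rep(NA_integer_, n_B)
    for (k in seq_len(n_B)) {
        if (coupled[k]) {
            placed <- FALSE
            for (a in seq_len(1000L)) {
                j <- sample.int(n_A, 1L)
                rad <- (r_A[j] + delta_px) * sqrt(runif(1))
                th <- runif(1, 0, 2 * pi)
                cand <- pos_A[j, ] + rad * c(cos(th), sin(th))
                if (points_in_cell(geom, cand[1], cand[2]) &&
                    distance_to_perimeter(geom, cand[1], cand[2]) >= r_B[k]) {
                    pos_B[k, ] <- cand; partner[k] <- j; placed <- TRUE; break
                }
            }
            if (!placed)
                stop("failed to place coupled B particle ", k, " within delta = ",
                     cfg$coupling_distance_nm, " nm at pixel size ", px,
                     " nm after 1000 attempts")
        } else {
            pos_B[k, ] <- sample_in_polygon_each(geom, r_B[k])
        }
    }

    ps_A <- draw_circles(pos_A[, 1], pos_A[, 2], area_A, dim, px, area_um2)
    ps_B <- draw_circles(pos_B[, 1], pos_B[, 2], area_B, dim, px, area_um2)

    gt <- data.frame(
        particle_id = c(seq_len(n_A), seq_len(n_B)),
        channel = rep(c("A", "B"), c(n_A, n_B)),
        cx_px = c(pos_A[, 1], pos_B[, 1]),
        cy_px = c(pos_A[, 2], pos_B[, 2]),
        target_area_nm2 = c(area_A, area_B),
        radius_px = c(r_A, r_B),
        coupled = c(rep(FALSE, n_A), coupled),
        partner = c(rep(NA_integer_, n_A), partner))

    list(A = ps_A, B = ps_B, ground_truth = gt,
         cell_area_um2 = area_um2, dim = dim, pixel_size_nm = px)
}

# rasterize thick segments: pixels whose centre is within width/2 of any
# segment; returns 0/1 matrix
rasterize_segments <- function(seg, dim, half_width_px) {
    m <- matrix(0L, dim[1], dim[2])
    for (e in seq_len(nrow(seg))) {
        ax <- seg[e, 1]; ay <- seg[e, 2]; bx <- seg[e, 3]; by <- seg[e, 4]
        j0 <- max(1L, floor(min(ax, bx) - half_width_px))
        j1 <- min(dim[2], ceiling(max(ax, bx) + half_width_px))
        i0 <- max(1L, floor(min(ay, by) - half_width_px))
        i1 <- min(dim[1], ceiling(max(ay, by) + half_width_px))
        if (j1 < j0 || i1 < i0) next
        cols <- j0:j1; rows <- i0:i1
        xs <- rep(cols - 0.5, each = length(rows))
        ys <- rep(rows - 0.5, times = length(cols))
        abx <- bx - ax; aby <- by - ay
        len2 <- abx^2 + aby^2
        t <- if (len2 > 0) pmin(1, pmax(0, ((xs - ax) * abx + (ys - ay) * aby) / len2)) else 0
        d2 <- (xs - (ax + t * abx))^2 + (ys - (ay + t * aby))^2
        hit <- d2 <= half_width_px^2
        if (any(hit)) {
            idx <- cbind(rep(rows, times = length(cols))[hit],
                         rep(cols, each = length(rows))[hit])
            m[idx] <- 1L
        }
    }
    m
}

#' Generate organelle masks for a synthetic cell
#'
#' Builds, on a common grid: the plasma-membrane band (interior pixels within
#' `pm_band_px` of the boundary), an ER tubule network (minimum spanning tree
#' over random anchor points, rasterized at a configurable tubule width,
#' default 150 nm — the ER tubule calibre reported for these cell types), ER
#' exit sites (sparse pixels on the ER), and a compact Golgi blob. All masks
#' are subsets of the cell interior and ERES is a subset of the ER.
#'
#' @param geom a [cell_geometry()].
#' @param pixel_size_nm pixel size in nm.
#' @param pm_band_px PM band width in pixels (0 gives an empty band; must be
#'   smaller than the cell inradius).
#' @param er list: `n_anchors` (default 12), `width_nm` (default 150),
#'   `n_extra_edges` (default 2) extra short-loop edges beyond the MST.
#' @param eres list: `n` (default 30) number of exit-site pixels.
#' @param golgi list: `radius_px` (default a fifth of the inradius).
#' @param seed integer RNG seed.
#' @param dim optional grid (nrow, ncol).
#' @return list of class `organelle_masks` with [binary_mask()] elements
#'   `interior`, `pm`, `er`, `eres`, `golgi`, plus `inradius_px`.
#' @export
make_organelle_masks <- function(geom, pixel_size_nm, pm_band_px = 5L,
                                 er = list(), eres = list(), golgi = list(),
                                 seed = 1L, dim = NULL) {
    stopifnot(inherits(geom, "cell_geometry"))
    er <- modifyList(list(n_anchors = 12L, width_nm = 150, n_extra_edges = 2L), er)
    eres <- modifyList(list(n = 30L), eres)
    dim <- geom_grid_dim(geom, dim)
    set.seed(seed)

    interior <- rasterize_polygon(geom, dim, pixel_size_nm)
    outside <- binary_mask(1L - interior$px, pixel_size_nm)
    d_out <- distance_map(outside)          # distance of interior px to exterior
    inradius_px <- max(d_out[interior$px == 1L])
    if (pm_band_px >= inradius_px)
        stop("PM band (", pm_band_px, " px) is wider than the cell inradius (",
             round(inradius_px, 1), " px)")
    pm <- binary_mask(interior$px == 1L & d_out <= pm_band_px, pixel_size_nm)

    golgi <- modifyList(list(radius_px = max(3, round(inradius_px / 5))), golgi)

    # ER: MST over anchors placed away from the boundary
    anchors <- sample_in_polygon(geom, er$n_anchors, r_px = pm_band_px + 2)
    dmat <- as.matrix(stats::dist(anchors))
    g <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                             weighted = TRUE)
    mst <- igraph::mst(g)
    el <- igraph::as_edgelist(mst, names = FALSE)
    if (er$n_extra_edges > 0L && er$n_anchors > 3L) {
        extra <- cbind(sample.int(er$n_anchors, er$n_extra_edges),
                       sample.int(er$n_anchors, er$n_extra_edges))
        extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
        el <- rbind(el, extra)
    }
    seg <- cbind(anchors[el[, 1], 1], anchors[el[, 1], 2],
                 anchors[el[, 2], 1], anchors[el[, 2], 2])
    half_w <- (er$width_nm / pixel_size_nm) / 2
    er_px <- rasterize_segments(seg, dim, half_w) * interior$px
    er_mask <- binary_mask(er_px, pixel_size_nm)

    # ERES: sparse pixels on the ER
    er_idx <- which(er_mask$px == 1L)
    eres_px <- matrix(0L, dim[1], dim[2])
    if (length(er_idx) > 0L && eres$n > 0L)
        eres_px[sample(er_idx, min(eres$n, length(er_idx)))] <- 1L
    eres_mask <- binary_mask(eres_px, pixel_size_nm)

    # Golgi: one compact blob with clearance from the boundary
    gc <- sample_in_polygon(geom, 1L, r_px = golgi$radius_px + 1)
    golgi_px <- paint_disks_cpp(dim[1], dim[2], gc[1, 1], gc[1, 2],
                                golgi$radius_px)
    golgi_mask <- binary_mask((golgi_px > 0L) * interior$px, pixel_size_nm)

    structure(list(interior = interior, pm = pm, er = er_mask,
                   eres = eres_mask, golgi = golgi_mask,
                   inradius_px = inradius_px),
              class = "organelle_masks")
}

#' Write simulation ground truth as CSV
#'
#' Columns: particle_id, channel, cx_px, cy_px, target_area_nm2, radius_px,
#' coupled, partner.
#'
#' @param sim result of [simulate_coupled_particles()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
    utils::write.csv(sim$ground_truth, path, row.names = FALSE)
    invisible(path)
}
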