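#' Redraw particles as equal-area circles at random positions in the cell
#'
#' The particle-preserving randomization null: every input particle is
#' redrawn as a circle of radius `sqrt(area/pi)` at a uniform random
#' position inside the cell perimeter. Particle number is conserved exactly;
#' per-particle area is conserved up to circle rasterization (the radius
#' stays continuous and the painted pixel count is reported, not corrected).
#' Whole footprints are kept inside the polygon (centre at least one radius
#' from the boundary) and circles are pairwise non-overlapping by default,
#' both via rejection sampling.
#'
#' @param ps a [particle_set()] to scramble.
#' @param geom a [cell_geometry()] (same pixel grid as `ps`).
#' @param seed integer RNG seed.
#' @param allow_overlap permit overlapping circles (escape hatch for
#'   pathologically dense inputs; the painted union area then under-reports
#'   the input area).
#' @param max_attempts placement attempts per particle before failing with a
#'   packing error (default 10000).
#' @return a [particle_set()] on the same grid with the same number of
#'   particles, in the input particle order.
#' @export
scramble_once <- function(ps, geom, seed, allow_overlap = FALSE,
                          max_attempts = 10000L) {
    stopifnot(is_particle_set(ps), inherits(geom, "cell_geometry"))
    n <- n_particles(ps)
    dim <- dim(ps$labels)
    px <- ps$pixel_size_nm
    if (n == 0L)
        return(particle_set(matrix(0L, dim[1], dim[2]), px, ps$cell_area_um2))
    set.seed(seed)
    r_px <- sqrt(ps$table$area_nm2 / pi) / px
    ord <- order(r_px, decreasing = TRUE)     # place large circles first
    bx <- range(geom$x); by <- range(geom$y)
    cx <- numeric(n); cy <- numeric(n)
    placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- numeric(0)
    for (k in ord) {
        r <- r_px[k]
        done <- FALSE
        attempts <- 0L
        while (attempts < max_attempts) {
            m <- min(256L, max_attempts - attempts)
            attempts <- attempts + m
            qx <- runif(m, bx[1], bx[2]); qy <- runif(m, by[1], by[2])
            ok <- points_in_cell(geom, qx, qy)
            if (any(ok))
                ok[ok] <- distance_to_perimeter(geom, qx[ok], qy[ok]) >= r
            if (!allow_overlap && any(ok) && length(placed_x) > 0) {
                for (i in which(ok)) {
                    if (any((qx[i] - placed_x)^2 + (qy[i] - placed_y)^2 <
                            (r + placed_r)^2)) ok[i] <- FALSE
                }
            }
            hit <- which(ok)
            if (length(hit) > 0) {
                cx[k] <- qx[hit[1]]; cy[k] <- qy[hit[1]]
                placed_x <- c(placed_x, cx[k]); placed_y <- c(placed_y, cy[k])
                placed_r <- c(placed_r, r)
                done <- TRUE
                break
            }
        }
        if (!done)
            stop("packing error: could not place particle ", ps$table$id[k],
                 " (radius ", round(r, 2), " px) after ", max_attempts,
                 " attempts; retry with a new seed or allow_overlap = TRUE")
    }
    labels <- paint_disks_cpp(dim[1], dim[2], cx, cy, r_px)
    particle_set(labels, px, ps$cell_area_um2)
}

#' Run several scrambling trials with conservation diagnostics
#'
#' Trial seeds are derived deterministically as `base_seed + trial_index`
#' (0-based index), so a run is reproducible from its base seed. Three
#' trials is the conventional default for averaging the null.
#'
#' @inheritParams scramble_once
#' @param n_trials number of trials (>= 1, default 3).
#' @param base_seed integer base seed.
#' @return object of class `scramble_result`: list with `n_trials`, `seeds`,
#'   `trials` (list of scrambled [particle_set()]s), `area_diff_pct`
#'   (per-trial `|area_out - area_in| / area_in * 100`),
#'   `mean_area_diff_pct`, `n_in`, `total_area_in_nm2`.
#' @export
scramble_trials <- function(ps, geom, n_trials = 3L, base_seed = 1L,
                            allow_overlap = FALSE, max_attempts = 10000L) {
    stopifnot(n_trials >= 1L)
    seeds <- base_seed + seq_len(n_trials) - 1L
    total_in <- sum(ps$table$area_nm2)
    trials <- lapply(seeds, function(s)
        scramble_once(ps, geom, s, allow_overlap, max_attempts))
    diffs <- vapply(trials, function(t)
        abs(sum(t$table$area_nm2) - total_in) / total_in * 100, numeric(1))
    structure(list(n_trials = n_trials, seeds = seeds, trials = trials,
                   area_diff_pct = diffs,
                   mean_area_diff_pct = mean(diffs),
                   n_in = n_particles(ps),
                   total_area_in_nm2 = total_in),
              class = "scramble_result")
}

#' @export
print.scramble_result <- function(x, ...) {
    cat(sprintf("<scramble_result> %d trials on %d particles, mean |area diff| %.3f%%\n",
                x$n_trials, x$n_in, x$mean_area_diff_pct))
    invisible(x)
}

#' Scrambled-baseline colocalization
#'
#' Scrambles channel A and recomputes [overlap_coloc()] against the genuine
#' channel B for each trial; reports the per-trial and averaged baseline
#' alongside the genuine value and the genuine-minus-baseline difference.
#' This is the control for whether observed colocalization exceeds what
#' particle number and sizes alone produce under complete spatial
#' randomness.
#'
#' @inheritParams scramble_trials
#' @param A a [particle_set()] (the channel being scrambled).
#' @param B a [binary_mask()] or [particle_set()] (the fixed partner).
#' @return list with `genuine` ([overlap_coloc()] result), `trials` (list of
#'   per-trial results), `baseline` (named numeric means over trials of the
#'   four percentages), and `difference` (genuine minus baseline).
#' @export
scrambled_baseline <- function(A, B, geom, n_trials = 3L, base_seed = 1L,
                               allow_overlap = FALSE, max_attempts = 10000L) {
    stopifnot(is_particle_set(A))
    genuine <- overlap_coloc(A, B)
    sc <- scramble_trials(A, geom, n_trials, base_seed, allow_overlap,
                          max_attempts)
    res <- lapply(sc$trials, overlap_coloc, B = B)
    fields <- c("object_pct_A_to_B", "object_pct_B_to_A",
                "area_pct_A_to_B", "area_pct_B_to_A")
    baseline <- vapply(fields, function(f)
        mean(vapply(res, `[[`, numeric(1), f)), numeric(1))
    difference <- vapply(fields, function(f) genuine[[f]], numeric(1)) - baseline
    list(genuine = genuine, trials = res, scramble = sc,
         baseline = baseline, difference = difference)
}
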