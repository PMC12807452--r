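# Shared fixture builders; everything is generated in code at test time.

# small binary mask from explicit foreground coordinates (1-based row, col)
mask_from_coords <- function(nr, nc, coords, pixel_size_nm = 10) {
    m <- matrix(0L, nr, nc)
    if (length(coords) > 0) m[coords] <- 1L
    binary_mask(m, pixel_size_nm)
}

# a mildly irregular test cell
test_cell <- function(seed = 1, radius_px = 100, irregularity = 0.2) {
    make_cell_geometry(seed = seed, radius_px = radius_px,
                       irregularity = irregularity)
}

# scrambler conservation fixture: n particles with lognormal pixel areas
# (median median_px pixels) drawn as disjoint circles inside the cell
scramble_fixture <- function(seed, n = 50, median_px = 16, sigma = 0.5,
                             radius_px = 100, pixel_size_nm = 30) {
    geom <- test_cell(seed = seed, radius_px = radius_px)
    set.seed(seed + 1000L)
    areas_px <- rlnorm(n, log(median_px), sigma)
    areas_nm2 <- areas_px * pixel_size_nm^2
    r_px <- sqrt(areas_px / pi)
    # non-overlapping placement so the fixture has exactly n particles
    cx <- numeric(n); cy <- numeric(n)
    bx <- range(geom$x); by <- range(geom$y)
    for (k in seq_len(n)) {
        repeat {
            x <- runif(1, bx[1], bx[2]); y <- runif(1, by[1], by[2])
            if (!points_in_cell(geom, x, y)) next
            if (distance_to_perimeter(geom, x, y) < r_px[k] + 1) next
            if (k > 1 && any(sqrt((x - cx[seq_len(k - 1)])^2 +
                                  (y - cy[seq_len(k - 1)])^2) <
                             r_px[k] + r_px[seq_len(k - 1)] + 1.5)) next
            cx[k] <- x; cy[k] <- y; break
        }
    }
    dim <- geom_dim <- attr(geom, "grid_dim")
    ps <- draw_circles(cx, cy, areas_nm2, dim, pixel_size_nm)
    list(geom = geom, ps = ps)
}

# brute-force nearest edge-to-edge distance oracle: all pixel pairs
brute_force_nnd <- function(psA, mB) {
    d <- matrix(NA_real_, 0, 0)
    idxB <- which(mB$px == 1L)
    rB <- (idxB - 1L) %% nrow(mB$px) + 1L
    cB <- (idxB - 1L) %/% nrow(mB$px) + 1L
    out <- numeric(nrow(psA$table))
    for (i in seq_len(nrow(psA$table))) {
        id <- psA$table$id[i]
        idxA <- which(psA$labels == id)
        rA <- (idxA - 1L) %% nrow(psA$labels) + 1L
        cA <- (idxA - 1L) %/% nrow(psA$labels) + 1L
        best <- Inf
        for (j in seq_along(idxA))
            best <- min(best, min((rA[j] - rB)^2 + (cA[j] - cB)^2))
        out[i] <- sqrt(best) * psA$pixel_size_nm
    }
    out
}

# independent (f = 0) two-channel scene for CSR-type checks
csr_scene <- function(seed, radius_px = 150, pixel_size_nm = 20,
                      density = 150, area_median_nm2 = 5000) {
    geom <- test_cell(seed = seed, radius_px = radius_px)
    cfg <- sim_config(pixel_size_nm = pixel_size_nm,
                      density_A = density, density_B = density,
                      coupling_fraction = 0,
                      area_median_nm2 = area_median_nm2,
                      area_sigma = 0.5, seed = seed)
    c(simulate_coupled_particles(geom, cfg), list(geom = geom))
}
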