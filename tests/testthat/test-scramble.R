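test_that("scrambling conserves particle count exactly, incl. empty input", {
    fx <- scramble_fixture(seed = 1, n = 40)
    out <- scramble_once(fx$ps, fx$geom, seed = 5)
    expect_equal(nrow(out$table), 40L)
    expect_identical(dim(out$labels), dim(fx$ps$labels))

    empty <- particle_set(matrix(0L, 50, 50), 30)
    geo <- test_cell(seed = 2, radius_px = 20)
    expect_equal(nrow(scramble_once(empty, geo, seed = 1)$table), 0L)
})

test_that("scrambled circles stay inside the perimeter, non-overlapping", {
    fx <- scramble_fixture(seed = 3, n = 30)
    out <- scramble_once(fx$ps, fx$geom, seed = 9)
    idx <- which(out$labels > 0L)
    r <- (idx - 1L) %% nrow(out$labels) + 1L
    c <- (idx - 1L) %/% nrow(out$labels) + 1L
    expect_true(all(points_in_cell(fx$geom, c - 0.5, r - 0.5)))
    # non-overlap: every particle keeps a full circle's worth of pixels
    expect_equal(nrow(out$table), 30L)
    expect_true(all(out$table$n_px > 0))
})

test_that("mean total-area difference stays below 1% on lognormal fixtures", {
    diffs <- vapply(1:3, function(s) {
        fx <- scramble_fixture(seed = s, n = 50)
        scramble_trials(fx$ps, fx$geom, n_trials = 3, base_seed = s)$mean_area_diff_pct
    }, numeric(1))
    expect_lt(mean(diffs), 1)
})

test_that("trials are deterministic and seeded on a ladder from the base", {
    fx <- scramble_fixture(seed = 4, n = 20)
    a <- scramble_trials(fx$ps, fx$geom, n_trials = 3, base_seed = 11)
    b <- scramble_trials(fx$ps, fx$geom, n_trials = 3, base_seed = 11)
    expect_identical(a$seeds, c(11, 12, 13))
    for (k in 1:3)
        expect_identical(a$trials[[k]]$labels, b$trials[[k]]$labels)

    # one trial wraps a single scramble_once with the base seed
    single <- scramble_trials(fx$ps, fx$geom, n_trials = 1, base_seed = 11)
    direct <- scramble_once(fx$ps, fx$geom, seed = 11)
    expect_identical(single$trials[[1]]$labels, direct$labels)

    # default trial count is 3
    expect_equal(formals(scramble_trials)$n_trials, 3L)
})

test_that("scrambled centroids are uniform over the cell interior", {
    geom <- test_cell(seed = 6, radius_px = 100)
    fx <- scramble_fixture(seed = 6, n = 20, median_px = 4, sigma = 0.2)
    n_trials <- 100                      # 2000 placements
    cx <- numeric(0); cy <- numeric(0)
    for (t in seq_len(n_trials)) {
        out <- scramble_once(fx$ps, fx$geom, seed = 1000 + t)
        cx <- c(cx, out$table$cx_px); cy <- c(cy, out$table$cy_px)
    }
    interior <- rasterize_polygon(fx$geom, dim(fx$ps$labels), 30)
    # expected occupancy per 4x4 bin from the interior raster
    nb <- 4
    xb <- seq(min(fx$geom$x), max(fx$geom$x), length.out = nb + 1)
    yb <- seq(min(fx$geom$y), max(fx$geom$y), length.out = nb + 1)
    ix <- which(interior$px == 1L)
    pxx <- ((ix - 1L) %/% nrow(interior$px)) + 0.5
    pyy <- ((ix - 1L) %% nrow(interior$px)) + 0.5
    bin <- function(x, y) {
        bx <- pmin(pmax(findInterval(x, xb, all.inside = TRUE), 1), nb)
        by <- pmin(pmax(findInterval(y, yb, all.inside = TRUE), 1), nb)
        table(factor(bx + nb * (by - 1), levels = 1:(nb * nb)))
    }
    expected_w <- as.numeric(bin(pxx, pyy))
    observed <- as.numeric(bin(cx, cy))
    keep <- expected_w > 0
    expected <- sum(observed) * expected_w[keep] / sum(expected_w[keep])
    x2 <- sum((observed[keep] - expected)^2 / expected)
    crit <- qchisq(0.99, df = sum(keep) - 1)
    expect_lt(x2, crit)
})

test_that("scrambled baseline: saturated partner, CSR null, coupled excess", {
    # B covering the whole cell -> baseline object colocalization 100%
    geom <- test_cell(seed = 7, radius_px = 60)
    fx <- scramble_fixture(seed = 7, n = 15, radius_px = 60)
    full <- rasterize_polygon(geom, dim(fx$ps$labels), 30)
    base <- scrambled_baseline(fx$ps, full, geom, n_trials = 2, base_seed = 3)
    expect_equal(unname(base$baseline["object_pct_A_to_B"]), 100)

    # independent channels: baseline area coloc matches CSR coverage (20 seeds)
    dev <- vapply(seq_len(20), function(s) {
        sc <- csr_scene(seed = 500 + s, radius_px = 120, density = 120)
        interior <- rasterize_polygon(sc$geom, dim(sc$A$labels), 20)
        mB <- rasterize(sc$B)
        expected <- 100 * sum(mB$px * interior$px) / sum(interior$px)
        bl <- scrambled_baseline(sc$A, mB, sc$geom, n_trials = 1,
                                 base_seed = s)
        unname(bl$baseline["area_pct_A_to_B"]) - expected
    }, numeric(1))
    expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(20))

    # coupled generator: genuine object coloc exceeds the scrambled baseline
    geom2 <- make_cell_geometry(seed = 8, radius_px = 500, irregularity = 0.15)
    cfg <- sim_config(pixel_size_nm = 5, density_A = 300, density_B = 300,
                      coupling_fraction = 0.6, coupling_distance_nm = 0,
                      area_median_nm2 = c(1691, 975), seed = 9)
    sim <- simulate_coupled_particles(geom2, cfg)
    bl <- scrambled_baseline(sim$B, rasterize(sim$A), geom2,
                             n_trials = 2, base_seed = 4)
    expect_gt(bl$genuine$object_pct_A_to_B,
              unname(bl$baseline["object_pct_A_to_B"]) + 20)
})
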