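test_that("overlap colocalization: identity, disjoint, hand-counted toy", {
    set.seed(21)
    A <- rasterize(draw_circles(c(20, 50, 80), c(20, 50, 80),
                                rep(3000, 3), c(100, 100), 10))
    self <- overlap_coloc(A, A)
    expect_equal(self$object_pct_A_to_B, 100)
    expect_equal(self$object_pct_B_to_A, 100)
    expect_equal(self$area_pct_A_to_B, 100)
    expect_equal(self$area_pct_B_to_A, 100)

    B <- mask_from_coords(100, 100, cbind(1:3, 1), 10)
    disj <- overlap_coloc(A, B)
    expect_equal(disj$object_pct_A_to_B, 0)
    expect_equal(disj$area_pct_A_to_B, 0)

    # 10x10 toy: A has 3 particles, exactly 2 touch B
    a <- mask_from_coords(10, 10, rbind(c(2, 2), c(5, 5), c(5, 6), c(9, 9)))
    b <- mask_from_coords(10, 10, rbind(c(2, 2), c(5, 6)))
    toy <- overlap_coloc(a, b)
    expect_equal(toy$n_A, 3)
    expect_equal(toy$object_pct_A_to_B, 200 / 3)

    expect_error(overlap_coloc(a, mask_from_coords(5, 5, NULL, 10)),
                 "grid mismatch")
})

test_that("compartment classification by centroid and any-pixel", {
    geom <- test_cell(seed = 12, radius_px = 80)
    om <- make_organelle_masks(geom, pixel_size_nm = 30, pm_band_px = 8,
                               seed = 3)
    dim <- dim(om$interior$px)

    # plant 46 of 100 puncta in the PM band, the rest well inside
    set.seed(77)
    pm_idx <- which(om$pm$px == 1L)
    deep_idx <- which(om$interior$px == 1L &
                      distance_map(binary_mask(1L - om$interior$px, 30)) > 12)
    pick <- c(sample(pm_idx, 46), sample(setdiff(deep_idx, pm_idx), 54))
    lab <- matrix(0L, dim[1], dim[2]); lab[pick] <- seq_along(pick)
    puncta <- particle_set(lab, 30)
    cls <- classify_by_mask(puncta, om$pm, mode = "centroid")
    expect_equal(cls$n_inside + cls$n_outside, 100)
    expect_equal(cls$pct_inside, 46)

    # all centroids inside the full interior -> 100%
    expect_equal(classify_by_mask(puncta, om$interior)$pct_inside, 100)
    # empty compartment -> 0%
    empty <- binary_mask(matrix(0L, dim[1], dim[2]), 30)
    expect_equal(classify_by_mask(puncta, empty)$pct_inside, 0)
    # empty puncta -> missing, not zero
    none <- particle_set(matrix(0L, dim[1], dim[2]), 30)
    expect_true(is.na(classify_by_mask(none, om$pm)$pct_inside))

    # any-pixel mode counts boundary-touching footprints
    two <- draw_circles(c(10, 40), c(10, 40), c(20000, 20000), c(80, 80), 30)
    target <- binary_mask(matrix(0L, 80, 80), 30)
    target$px[8:12, 8:12] <- 1L
    expect_equal(classify_by_mask(two, target, "any-pixel")$n_inside, 1)
})

test_that("nearest distances match arithmetic and the brute-force oracle", {
    # two 1-px particles 10 px apart at 5 nm/px -> centroid distance 50 nm
    a1 <- matrix(0L, 20, 20); a1[5, 3] <- 1L
    b1 <- matrix(0L, 20, 20); b1[5, 13] <- 1L
    psa <- particle_set(a1, 5); psb <- particle_set(b1, 5)
    expect_equal(nearest_distances(psa, psb, "centroid"), 50)
    expect_equal(nearest_distances(psa, psb, "edge"), 50)

    # overlapping particles -> 0 under the edge metric
    ov1 <- draw_circles(10, 10, 2000, c(30, 30), 10)
    ov2 <- draw_circles(10.5, 10, 2000, c(30, 30), 10)
    expect_equal(nearest_distances(ov1, ov2, "edge"), 0)

    # oracle equivalence on a ~50-particle fixture (exact)
    fx <- scramble_fixture(seed = 42, n = 25, radius_px = 60,
                           pixel_size_nm = 10)
    fy <- scramble_fixture(seed = 43, n = 25, radius_px = 60,
                           pixel_size_nm = 10)
    dims <- dim(fx$ps$labels)
    mB <- binary_mask(fy$ps$labels[seq_len(dims[1]), seq_len(dims[2])] > 0, 10)
    got <- nearest_distances(fx$ps, mB, "edge")
    expect_equal(got, brute_force_nnd(fx$ps, mB))

    expect_error(nearest_distances(psa, particle_set(matrix(0L, 20, 20), 5)),
                 "empty")
})

test_that("fraction within distance equals the dilation-based count", {
    fx <- scramble_fixture(seed = 51, n = 30, radius_px = 70,
                           pixel_size_nm = 10)
    fy <- scramble_fixture(seed = 52, n = 30, radius_px = 70,
                           pixel_size_nm = 10)
    dims <- dim(fx$ps$labels)
    mB <- binary_mask(fy$ps$labels[seq_len(dims[1]), seq_len(dims[2])] > 0, 10)

    expect_equal(fraction_within(fx$ps, mB, Inf), 100)
    for (d_nm in c(0, 30, 100, 250)) {
        frac <- fraction_within(fx$ps, mB, d_nm)
        dil <- dilate_mask(mB, d_nm / 10)
        touching <- unique(fx$ps$labels[dil$px == 1L & fx$ps$labels > 0L])
        expect_equal(frac, 100 * length(touching) / nrow(fx$ps$table),
                     label = paste("d =", d_nm))
    }
    # non-decreasing in d
    fr <- vapply(c(0, 20, 50, 100, 200, 400), function(d)
        fraction_within(fx$ps, mB, d), numeric(1))
    expect_true(all(diff(fr) >= 0))
})

test_that("ring profile: monotone cumulative occupancy, exact normalization", {
    geom <- test_cell(seed = 61, radius_px = 120)
    cfg <- sim_config(pixel_size_nm = 10, density_A = 40, density_B = 60,
                      coupling_fraction = 0.7, coupling_distance_nm = 40,
                      area_median_nm2 = 3000, seed = 62)
    sim <- simulate_coupled_particles(geom, cfg)
    rp <- ring_profile(sim$A, rasterize(sim$B))
    expect_true(all(diff(rp$raw) >= 0))
    expect_equal(rp$normalized[nrow(rp)], 1)
    expect_true(all(rp$raw >= 0 & rp$raw <= 1))

    # B inside A -> constant raw profile, normalized all 1
    A <- rasterize(draw_circles(30, 30, 20000, c(60, 60), 10))
    B <- rasterize(draw_circles(30, 30, 3000, c(60, 60), 10))
    rp2 <- ring_profile(A, B)
    expect_true(all(rp2$raw == rp2$raw[1]))
    expect_true(all(rp2$normalized == 1))

    # empty B: raw zeros, normalization undefined
    empty <- binary_mask(matrix(0L, 60, 60), 10)
    rp3 <- ring_profile(A, empty)
    expect_true(all(rp3$raw == 0))
    expect_true(all(is.na(rp3$normalized)))

    expect_error(ring_profile(A, B, radii_nm = c(40, 20)), "increasing")
})

test_that("tightly coupled channels saturate the ring profile early", {
    geom <- test_cell(seed = 71, radius_px = 300)
    cfg <- sim_config(pixel_size_nm = 5, density_A = 120, density_B = 120,
                      coupling_fraction = 1, coupling_distance_nm = 30,
                      area_median_nm2 = c(1691, 975), seed = 72)
    sim <- simulate_coupled_particles(geom, cfg)
    rp <- ring_profile(sim$A, rasterize(sim$B))
    expect_gte(rp$normalized[rp$radius_nm == 40], 0.9)
})

test_that("annulus profile is the difference of the cumulative profile", {
    rp <- structure(data.frame(radius_nm = c(20, 40, 60),
                               radius_px = c(2, 4, 6),
                               raw = c(0.2, 0.5, 1.0),
                               normalized = c(0.2, 0.5, 1.0)),
                    class = c("ring_profile", "data.frame"))
    ann <- annulus_profile(rp)
    expect_equal(ann$annulus, c(0.2, 0.3, 0.5))
    expect_equal(sum(ann$annulus), rp$raw[3])         # telescoping
    expect_true(all(ann$annulus >= 0))
})

test_that("area colocalization of independent channels matches CSR coverage", {
    n_seeds <- 20
    dev <- vapply(seq_len(n_seeds), function(s) {
        sc <- csr_scene(seed = 300 + s)
        interior <- rasterize_polygon(sc$geom, dim(sc$A$labels), 20)
        mB <- rasterize(sc$B)
        expected <- 100 * sum(mB$px * interior$px) / sum(interior$px)
        overlap_coloc(sc$A, mB)$area_pct_A_to_B - expected
    }, numeric(1))
    expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(n_seeds))
})

test_that("object colocalization recovers the generator coupling fraction", {
    # f sweep at delta = 0; estimator is the B->A object percentage
    f_grid <- c(0, 0.5, 1)
    for (f in f_grid) {
        est <- vapply(1:4, function(s) {
            geom <- make_cell_geometry(seed = 800 + s, radius_px = 700,
                                       irregularity = 0.15)
            cfg <- sim_config(pixel_size_nm = 5, density_A = 400,
                              density_B = 400, coupling_fraction = f,
                              coupling_distance_nm = 0,
                              area_median_nm2 = c(1691, 975),
                              n_B = 210, seed = 900 + s)
            sim <- simulate_coupled_particles(geom, cfg)
            overlap_coloc(sim$B, sim$A)$object_pct_A_to_B
        }, numeric(1))
        expect_lt(abs(mean(est) - 100 * f), 5, label = paste("f =", f))
    }
})
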