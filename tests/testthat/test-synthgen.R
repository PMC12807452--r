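test_that("cell geometry: regular polygon area, determinism, bounds", {
    reg <- make_cell_geometry(seed = 1, radius_px = 100, irregularity = 0)
    expect_lt(abs(reg$area_px2 - pi * 100^2) / (pi * 100^2), 0.02)

    g1 <- make_cell_geometry(seed = 7, radius_px = 80, irregularity = 0.3)
    g2 <- make_cell_geometry(seed = 7, radius_px = 80, irregularity = 0.3)
    expect_identical(g1$x, g2$x)
    expect_identical(g1$y, g2$y)

    expect_error(make_cell_geometry(seed = 1, radius_px = 5), "at least 10")
    expect_error(make_cell_geometry(seed = 1, radius_px = 50, irregularity = 1),
                 "irregularity")
})

test_that("organelle masks: containment, PM band edge cases, inradius guard", {
    geom <- test_cell(seed = 2, radius_px = 60)
    om <- make_organelle_masks(geom, pixel_size_nm = 30, pm_band_px = 4,
                               seed = 5)
    inside <- om$interior$px
    for (nm in c("pm", "er", "eres", "golgi"))
        expect_true(all(om[[nm]]$px <= inside), info = nm)
    # ERES strictly on the ER
    expect_true(all(om$eres$px * (1L - om$er$px) == 0L))
    expect_gt(sum(om$er$px), 0)
    expect_gt(sum(om$golgi$px), 0)

    om0 <- make_organelle_masks(geom, pixel_size_nm = 30, pm_band_px = 0,
                                seed = 5)
    expect_equal(sum(om0$pm$px), 0L)

    expect_error(make_organelle_masks(geom, pixel_size_nm = 30,
                                      pm_band_px = 1000, seed = 5),
                 "inradius")
})

test_that("ER tubules rasterize at the configured physical width", {
    # 150 nm at 30 nm/px -> 5 px across, measured on a horizontal tubule
    seg <- cbind(10.5, 20.5, 60.5, 20.5)
    m <- spotcoloc:::rasterize_segments(seg, c(40, 80), (150 / 30) / 2)
    widths <- colSums(m)[colSums(m) > 0]
    interior_cols <- widths[3:(length(widths) - 2)]
    expect_true(all(interior_cols == 5))
})

test_that("coupled simulation honours f = 0, ground-truth flags, containment", {
    geom <- test_cell(seed = 4, radius_px = 150)
    cfg <- sim_config(pixel_size_nm = 20, density_A = 100, density_B = 100,
                      coupling_fraction = 0, area_median_nm2 = 4000,
                      seed = 9)
    sim <- simulate_coupled_particles(geom, cfg)
    gt_b <- subset(sim$ground_truth, channel == "B")
    expect_equal(sum(gt_b$coupled), 0L)

    # every painted footprint pixel lies inside the polygon
    for (ch in c("A", "B")) {
        idx <- which(sim[[ch]]$labels > 0L)
        r <- (idx - 1L) %% nrow(sim[[ch]]$labels) + 1L
        c <- (idx - 1L) %/% nrow(sim[[ch]]$labels) + 1L
        expect_true(all(points_in_cell(geom, c - 0.5, r - 0.5)), info = ch)
    }

    # bit-identical regeneration under the same config
    sim2 <- simulate_coupled_particles(geom, cfg)
    expect_identical(sim$A$labels, sim2$A$labels)
    expect_identical(sim$B$labels, sim2$B$labels)
})

test_that("realized counts follow the requested Poisson densities", {
    geom <- test_cell(seed = 6, radius_px = 120)
    area <- cell_area_um2(geom, 20)
    lambda <- 120 * area / 100
    n_seeds <- 20
    counts <- vapply(seq_len(n_seeds), function(s) {
        cfg <- sim_config(pixel_size_nm = 20, density_A = 120, density_B = 0,
                          area_median_nm2 = 3000, seed = 100 + s)
        nrow(simulate_coupled_particles(geom, cfg)$ground_truth)
    }, numeric(1))
    # mean of n_seeds Poisson(lambda) draws within 3 sigma
    expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / n_seeds))
})

test_that("expected counts match printed transcript densities at scale", {
    # densities 134 and 33 per 100 um^2 on a large cell: expectation check
    geom <- test_cell(seed = 8, radius_px = 400)  # at 50 nm/px -> ~1250 um^2
    area <- cell_area_um2(geom, 50)
    cfg <- sim_config(pixel_size_nm = 50, density_A = 134, density_B = 33,
                      area_median_nm2 = 40000, seed = 21)
    sim <- simulate_coupled_particles(geom, cfg)
    gt <- sim$ground_truth
    for (ch in c("A", "B")) {
        lambda <- ifelse(ch == "A", 134, 33) * area / 100
        expect_lt(abs(sum(gt$channel == ch) - lambda), 3 * sqrt(lambda),
                  label = paste("channel", ch))
    }
})

test_that("rasterized circles hit their target pixel areas", {
    # area 400 nm^2 at 5 nm/px -> radius 2.257 px; brute-force oracle
    brute <- function(cx, cy, r) {
        g <- expand.grid(x = seq_len(40) - 0.5, y = seq_len(40) - 0.5)
        sum((g$x - cx)^2 + (g$y - cy)^2 <= r^2)
    }
    r_px <- sqrt(400 / pi) / 5
    ps <- draw_circles(20.3, 19.7, 400, c(40, 40), 5)
    expect_equal(ps$table$n_px, brute(20.3, 19.7, r_px))
    expect_true(abs(ps$table$n_px - 16) <= 3)   # pi r^2 = 16 px up to rounding

    # empty set -> all-zero mask
    empty <- draw_circles(numeric(0), numeric(0), numeric(0), c(10, 10), 5)
    expect_equal(sum(rasterize(empty)$px), 0L)
    expect_equal(nrow(empty$table), 0L)

    # two disjoint particles survive a label round trip
    two <- draw_circles(c(10, 30), c(10, 30), c(400, 400), c(40, 40), 5)
    m <- rasterize(two)
    expect_equal(attr(m, "n_components"), 2L)
    back <- label_particles(m, 8)
    expect_equal(nrow(back$table), 2L)
    expect_equal(sum(back$table$n_px), sum(two$table$n_px))
})
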