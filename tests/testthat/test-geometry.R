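test_that("satellite placement is tangent, non-overlapping and reproducible", {
  cfg <- assembly_config("satellite", n_zno = 215)
  for (seed in c(1, 7, 19, 101)) {
    m <- build_assembly(cfg, seed = seed)
    expect_equal(nrow(m$np_centers), 215)
    # centers sit exactly on the tangency sphere R + r
    expect_equal(sqrt(rowSums(m$np_centers^2)),
                 rep(42.5, 215), tolerance = 1e-9)
    # exhaustive pairwise check: no two centers closer than one diameter
    D <- as.matrix(dist(m$np_centers))
    diag(D) <- Inf
    expect_gte(min(D), 5)
  }
  m1 <- build_assembly(cfg, seed = 3)
  m2 <- build_assembly(cfg, seed = 3)
  expect_identical(m1$np_centers, m2$np_centers)
  m3 <- build_assembly(cfg, seed = 4)
  expect_false(identical(m1$np_centers, m3$np_centers))
})

test_that("degenerate and infeasible satellite configs are handled", {
  m0 <- build_assembly(assembly_config("satellite", n_zno = 0))
  expect_equal(nrow(geometry_bodies(m0)), 1L)
  expect_error(assembly_config("satellite", n_zno = 1e5), "infeasible")
  # passes the loose footprint check but cannot actually be packed
  cfg <- assembly_config("satellite", sio2_diameter = 8, zno_np_diameter = 5,
                         n_zno = 24)
  expect_error(build_assembly(cfg, seed = 1, max_attempts = 500), "attempts")
})

test_that("powder shell carries the volume of 215 satellite nanoparticles", {
  t <- equal_volume_shell_thickness(40, 2.5, 215)
  expect_equal(round(t, 1), 0.7)
  m <- build_assembly(assembly_config("powder", n_nanosystems = 1), seed = 2)
  b <- geometry_bodies(m)
  expect_equal(nrow(b), 2L)  # core + shell
  vol_shell <- 4 / 3 * pi * (m$shell_outer^3 - m$core_radius^3)
  vol_nps <- 215 * 4 / 3 * pi * 2.5^3
  expect_equal(vol_shell, vol_nps, tolerance = 0.03)
})

test_that("powder packing is contained, non-overlapping and gives tens-of-nm gaps", {
  m <- build_assembly(assembly_config("powder", n_nanosystems = 1500), seed = 5)
  expect_equal(nrow(m$centers), 1500)
  rho <- sqrt(m$centers[, 1]^2 + m$centers[, 2]^2)
  expect_true(all(rho <= m$cyl_radius - m$shell_outer + 1e-9))
  expect_true(all(abs(m$centers[, 3]) <= m$cyl_half_height - m$shell_outer + 1e-9))
  D <- as.matrix(dist(m$centers))
  diag(D) <- Inf
  expect_gte(min(D), 2 * m$shell_outer)
  # nearest-neighbour surface gap of order tens of nm (dilute hard spheres)
  gap <- mean(apply(D, 1, min)) - 2 * m$shell_outer
  expect_within(gap, 5, 200)
  expect_error(
    build_assembly(assembly_config("powder", n_nanosystems = 5e4,
                                   holder_diameter_um = 0.5,
                                   holder_height_um = 0.5)),
    "packing|dense|place")
})

test_that("point location matches a brute-force distance oracle", {
  m <- build_assembly(assembly_config("satellite", n_zno = 100,
                                      world_radius = 300), seed = 13)
  set.seed(42)
  pts <- matrix(runif(3 * 500, -310, 310), ncol = 3)
  got <- locate(m, pts)
  r <- sqrt(rowSums(pts^2))
  oracle <- rep("air", nrow(pts))
  oracle[r > 300] <- "outside"
  oracle[r <= 40] <- "SiO2"
  for (i in seq_len(nrow(pts))) {
    d2 <- colSums((t(m$np_centers) - pts[i, ])^2)
    if (any(d2 <= 2.5^2) && r[i] <= 300) oracle[i] <- "ZnO"
  }
  expect_identical(got$medium, oracle)
})

test_that("powder locate resolves the 0.7 nm shell", {
  m <- build_assembly(assembly_config("powder", n_nanosystems = 50), seed = 8)
  c1 <- m$centers[1, ]
  got <- locate(m, rbind(c1, c1 + c(40.35, 0, 0), c1 + c(45, 0, 0)))
  expect_identical(got$medium, c("SiO2", "ZnO", "air"))
  expect_identical(got$body[1:2], c(1L, 1L))
})

test_that("ray segmentation matches chord lengths and dense sampling", {
  m0 <- single_sphere_model(40, 200)
  seg <- ray_segments(m0, c(0, 0, -199), c(0, 0, 1))
  sio2 <- seg[seg$medium == "SiO2", ]
  expect_equal(nrow(sio2), 1L)
  expect_equal(sio2$length, 80, tolerance = 1e-9)
  # total length equals origin-to-exit distance
  expect_equal(sum(seg$length), 199 + 200, tolerance = 1e-6 * 399)
  # fine-step sampling oracle: per-medium occupancy along the ray
  m <- build_assembly(assembly_config("satellite", n_zno = 100,
                                      world_radius = 150), seed = 21)
  origin <- c(-149, 3, 2)
  dir <- c(1, 0, 0)
  seg <- ray_segments(m, origin, dir)
  tt <- seq(1e-4, sum(seg$length) - 1e-4, by = 0.02)
  pts <- cbind(origin[1] + tt, origin[2], origin[3])
  occ <- table(factor(locate(m, pts)$medium, levels = c("air", "SiO2", "ZnO")))
  expected <- tapply(seg$length, factor(seg$medium,
                                        levels = c("air", "SiO2", "ZnO")),
                     sum)
  expected[is.na(expected)] <- 0
  expect_equal(as.numeric(occ) * 0.02, as.numeric(expected), tolerance = 0.01)
  expect_error(ray_segments(m, origin, c(1, 1, 0)), "unit")
  # origin outside the world: empty segment list
  expect_equal(nrow(ray_segments(m, c(0, 0, 500), c(0, 0, -1))), 0L)
})

test_that("a diameter ray through a coated sphere sees both shell crossings", {
  m <- build_assembly(assembly_config("powder", n_nanosystems = 20), seed = 31)
  c1 <- m$centers[1, ]
  seg <- ray_segments(m, c1 - c(100, 0, 0), c(1, 0, 0))
  seg <- seg[seg$t0 >= 0 & seg$length > 1e-9, ]
  hit <- seg[seg$medium != "air", ]
  expect_identical(hit$medium[1:3], c("ZnO", "SiO2", "ZnO"))
  expect_equal(hit$length[c(1, 3)],
               rep(equal_volume_shell_thickness(40, 2.5, 215), 2),
               tolerance = 1e-9)
  expect_equal(hit$length[2], 80, tolerance = 1e-9)
})

test_that("Monte Carlo volume estimates match the analytic solids", {
  m <- toy_satellite(n_zno = 215, world_radius = 60)
  set.seed(99)
  n <- 2e5
  pts <- matrix(runif(3 * n, -60, 60), ncol = 3)
  med <- locate(m, pts)$medium
  v_box <- 120^3
  v_host <- mean(med == "toy10") * v_box
  v_np <- mean(med == "toy20") * v_box
  a_host <- 4 / 3 * pi * 40^3
  a_np <- 215 * 4 / 3 * pi * 2.5^3
  p <- a_host / v_box
  expect_lt(abs(v_host - a_host), 3 * v_box * sqrt(p * (1 - p) / n))
  p2 <- a_np / v_box
  expect_lt(abs(v_np - a_np), 3 * v_box * sqrt(p2 * (1 - p2) / n))
})
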