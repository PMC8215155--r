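# grid probing: rasterization, accessibility, volume, S/V, profile,
# constrictions

test_that("rasterization matches a brute-force distance check", {
  cut <- structure(list(
    atoms = atomset(rbind(c(0, 0, 10))), n_kept = 1L, n_total = 1L,
    frame = tunnel_frame(c(0, 0, 0), c(0, 0, 1), 20)),
    class = "ribosome_cutout")
  g <- rasterize(cut, spacing = 1, probe_radius = 4)
  # cell centres within vdW 1.7 + probe 4 = 5.7 A of the atom are ATOM
  dims <- g$dims
  idx <- seq_len(prod(dims)) - 1L
  ctr <- cbind(idx %% dims[1], (idx %/% dims[1]) %% dims[2],
               idx %/% (dims[1] * dims[2]))
  ctr <- sweep((ctr + 0.5) * g$spacing, 2, -g$origin)
  d <- sqrt((ctr[, 1] - 0)^2 + (ctr[, 2] - 0)^2 + (ctr[, 3] - 10)^2)
  expect_identical(g$labels == 1L, d <= 5.7)
  expect_error(rasterize(cut, spacing = 5, probe_radius = 4), "spacing")
})

test_that("closed hollow shell: interior is cavity, exterior outside", {
  # sphere of pseudo-atoms of radius 12 centred on the seed
  n <- 800
  set.seed(2)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- 12 * u / sqrt(rowSums(u^2))
  # dense enough shell: add a jittered second layer
  shell <- rbind(u, u * (14 / 12))
  cut <- structure(list(
    atoms = atomset(shell), n_kept = nrow(shell), n_total = nrow(shell),
    frame = tunnel_frame(c(0, 0, 0), c(0, 0, 1), 20)),
    class = "ribosome_cutout")
  g <- rasterize(cut, spacing = 1, probe_radius = 3)
  cav <- probe_accessibility(g, rotations = 3, seed = 1)
  lab <- cav$labels
  dims <- cav$dims
  idx <- seq_len(prod(dims)) - 1L
  ctr <- cbind(idx %% dims[1], (idx %/% dims[1]) %% dims[2],
               idx %/% (dims[1] * dims[2]))
  ctr <- sweep((ctr + 0.5) * cav$spacing, 2, -cav$origin)
  r <- sqrt(rowSums(ctr^2))
  expect_true(all(lab[r < 6] == 3L))          # deep interior is cavity
  # far exterior (beyond the probe-inflated shell) is outside
  expect_true(all(lab[r > 19.2] == 2L))
})

test_that("straight-tube volume matches the analytic oracle at both probes", {
  tun <- make_toy_tunnel(length = 80, radius = 10, seed = 1)
  for (p in c(4, 3)) {
    g <- rasterize(tun, spacing = 1, probe_radius = p)
    cav <- probe_accessibility(g, rotations = 5, seed = 1)
    v <- tunnel_volume(cav)
    analytic <- pi * (10 - p)^2 * 80
    expect_lt(abs(v$volume - analytic) / analytic, 0.10)
  }
})

test_that("volume decreases monotonically with probe radius", {
  tun <- make_toy_tunnel(length = 50, radius = 9,
                         waists = data.frame(z = 25, r = 7), seed = 4)
  vols <- vapply(c(3, 3.5, 4), function(p) {
    cav <- probe_accessibility(rasterize(tun, 1, p), rotations = 3, seed = 1)
    tunnel_volume(cav)$volume
  }, numeric(1))
  expect_true(all(diff(vols) < 0))
})

test_that("volume is stable under rigid rotation and grid refinement", {
  tun <- make_toy_tunnel(length = 40, radius = 9, seed = 6)
  g1 <- rasterize(tun, spacing = 1, probe_radius = 4)
  v1 <- tunnel_volume(probe_accessibility(g1, rotations = 3, seed = 1))$volume
  # rotate the wall atoms rigidly and recompute
  set.seed(9)
  R <- ribotunnel:::.random_rotation()
  at <- tun$atoms
  xyz <- cbind(at$x, at$y, at$z) %*% t(R)
  tun2 <- tun
  tun2$atoms$x <- xyz[, 1]; tun2$atoms$y <- xyz[, 2]; tun2$atoms$z <- xyz[, 3]
  g2 <- rasterize(tun2, spacing = 1, probe_radius = 4)
  v2 <- tunnel_volume(probe_accessibility(
    g2, rotations = 3, seed = 1,
    seed_point = as.numeric(R %*% c(0, 0, 0.5))))$volume
  expect_lt(abs(v1 - v2) / v1, 0.05)
  # halving the spacing moves the estimate by < 5%
  g05 <- rasterize(tun, spacing = 0.5, probe_radius = 4)
  v05 <- tunnel_volume(probe_accessibility(g05, rotations = 3,
                                           seed = 1))$volume
  expect_lt(abs(v05 - v1) / v1, 0.05)
})

# cavity_map with hand-set labels, for closed-form surface checks
synthetic_cavity <- function(dims, cavity_cells, spacing = 1) {
  lab <- rep(1L, prod(dims))
  idx <- cavity_cells[, 1] + dims[1] * (cavity_cells[, 2] +
                                          dims[2] * cavity_cells[, 3]) + 1L
  lab[idx] <- 3L
  structure(list(labels = lab, dims = as.integer(dims), origin = c(0, 0, 0),
                 spacing = spacing, probe = 4, n_rotations = 1,
                 volumes = sum(lab == 3L) * spacing^3, combine = "majority"),
            class = "cavity_map")
}

test_that("surface-to-volume matches closed forms on synthetic label grids", {
  # a single enclosed cavity cell: ratio = 6 / spacing
  one <- synthetic_cavity(c(3, 3, 3), cbind(1, 1, 1), spacing = 2)
  expect_equal(surface_to_volume(one), 6 / 2)
  # long square duct of side L cells: ratio -> 4 / (L * spacing)
  L <- 3; M <- 60
  cells <- as.matrix(expand.grid(1:L, 1:L, 1:M))
  duct <- synthetic_cavity(c(L + 2, L + 2, M + 2), cells)
  expected <- (4 * L * M + 2 * L^2) / (L^2 * M)   # exact, incl. end caps
  expect_equal(surface_to_volume(duct), expected)
  expect_lt(abs(expected - 4 / L), 0.04)
})

test_that("surface-to-volume of a probed tube sits in the staircase band", {
  # voxelised lateral surface of a cylinder exceeds the smooth value by up
  # to 4/pi; the cavity radius is (10 - 4) = 6 A
  tun <- make_toy_tunnel(length = 100, radius = 10, seed = 8)
  cav <- probe_accessibility(rasterize(tun, 1, 4), rotations = 3, seed = 1)
  sv <- surface_to_volume(cav)
  expect_gt(sv, 2 / 6 * 0.95)
  expect_lt(sv, 2 / 6 * (4 / pi) * 1.35)
})

test_that("axial profile recovers a uniform tube radius", {
  tun <- make_toy_tunnel(length = 60, radius = 10, seed = 2)
  cav <- probe_accessibility(rasterize(tun, 1, 4), rotations = 3, seed = 1)
  prof <- axial_profile(cav, bin_width = 2)
  inner <- prof[prof$z > 10 & prof$z < 50, ]
  # probe-centre radius = 10 - 4 = 6
  expect_true(all(abs(inner$r_eff - 6) < 1))
  expect_true(all(prof$area >= 0))
})

test_that("constructed waists are recovered as CS1/CS2 within 2 A", {
  tun <- make_toy_tunnel(length = 80, radius = 18,
                         waists = data.frame(z = c(30, 50), r = c(8, 15)),
                         seed = 2)
  cav <- probe_accessibility(rasterize(tun, 1, 4), rotations = 5, seed = 1)
  prof <- axial_profile(cav, bin_width = 2)
  cs <- find_constrictions(prof, z_range = c(4, 76))
  expect_gte(nrow(cs), 2)
  expect_lt(abs(cs$z[1] - 30), 2 + 1e-9)
  expect_lt(abs(cs$z[2] - 50), 2 + 1e-9)
  expect_identical(cs$rank[1:2], c("CS1", "CS2"))
  # ranks are ordered by increasing z
  expect_true(!is.unsorted(cs$z))
})

test_that("a strictly widening cone has no constrictions", {
  prof <- structure(
    tibble::tibble(z = seq(1, 59, by = 2),
                   area = pi * (2 + 0.2 * seq(1, 59, by = 2))^2,
                   r_eff = 2 + 0.2 * seq(1, 59, by = 2)),
    class = c("tunnel_profile", class(tibble::tibble())),
    bin_width = 2, spacing = 1)
  expect_equal(nrow(find_constrictions(prof)), 0)
})

test_that("cavity is a single 6-connected component containing the seed", {
  tun <- make_toy_tunnel(length = 40, radius = 8, seed = 5)
  cav <- probe_accessibility(rasterize(tun, 1, 4), rotations = 3, seed = 1)
  lab <- cav$labels
  # re-flood from any cavity cell reaches every cavity cell
  first <- which(lab == 3L)[1]
  relab <- ifelse(lab == 3L, 0L, lab)
  refill <- ribotunnel:::cpp_flood_fill(
    relab, rep(FALSE, length(lab)), cav$dims, first - 1L)
  expect_identical(refill == 3L, lab == 3L)
})
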