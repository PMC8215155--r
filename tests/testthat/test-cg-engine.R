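# potential terms, integrator, growth and determinism of the engine

params <- sim_params()

test_that("bond and contact wells have the stated minima", {
  dimer <- native_model_from_ca(rbind(c(0, 0, 0), c(0, 0, 3.8)), cutoff = 0)
  r <- bonded_energy(rbind(c(0, 0, 0), c(0, 0, 3.8)), dimer, params)
  expect_equal(r$energy, 0)
  expect_equal(max(abs(r$forces)), 0)
  # a native contact at its native distance: energy -eps, zero force
  nat <- native_model_from_ca(
    rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 0),
          c(0, 0, 5.5)), cutoff = 6, min_sep = 3)
  stopifnot(nrow(nat$contacts) >= 1)
  ce <- contact_energy(nat$xyz, nat, params)
  expect_equal(ce$terms[["contacts"]], -nrow(nat$contacts) * params$epsilon,
               tolerance = 1e-12)
  expect_true(all(ce$formed))
})

test_that("contact formed flag flips exactly at 1.5 s_ij", {
  nat <- native_model_from_ca(
    rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(0, 0, 6.0)),
    cutoff = 6.5, min_sep = 3)
  expect_equal(nrow(nat$contacts), 1)  # pair (1, 4) at 6.0 A
  s <- 6.0 * 2^(-1 / 6)
  place <- function(d) {
    x <- nat$xyz
    x[4, ] <- c(0, 0, d)
    x
  }
  expect_false(contact_energy(place(1.5 * s), nat, params)$formed)
  expect_true(contact_energy(place(1.5 * s - 1e-6), nat, params)$formed)
})

test_that("native conformation has zero chirality energy", {
  nat <- make_toy_native("helix", 15, seed = 1)
  r <- bonded_energy(nat$xyz, nat, params)
  # bonds are at their native lengths only up to the 3.8-A rescaling, so
  # compare the chirality component alone
  x <- nat$xyz
  ch <- ribotunnel:::cpp_energy_forces(
    x, unclass(nat), unclass(params), NULL, "chirality", NULL, -1L)
  expect_equal(ch$energy, 0)
})

test_that("wall potentials take their closed-form values", {
  s0 <- params$sigma0
  w <- wall_field(NULL, plate = TRUE)
  nat <- native_model_from_ca(rbind(c(0, 0, s0), c(0, 0, s0 + 3.8)),
                              cutoff = 0)
  r <- wall_energy(rbind(c(0, 0, s0), c(50, 50, 1e6)), w, params)
  # bead at z = sigma0: plate energy exactly wall_amp * eps
  expect_equal(r$terms[["plate"]], 332, tolerance = 1e-9)
  # bead exactly 4 A from a single wall atom: zero energy and force
  tun <- structure(list(atoms = atomset(rbind(c(0, 0, 10))), n_kept = 1L,
                        n_total = 1L,
                        frame = tunnel_frame(c(0, 0, 0), c(0, 0, 1), 20)),
                   class = "ribosome_cutout")
  wf <- wall_field(tun, plate = FALSE)
  r2 <- wall_energy(rbind(c(4, 0, 10), c(0, 4 + 1e-9, 10)), wf, params)
  expect_equal(r2$energy, 0, tolerance = 1e-9)
  expect_equal(max(abs(r2$forces)), 0, tolerance = 1e-6)
  expect_error(wall_energy(rbind(c(0, 0, -1)), w, params), "penetration")
})

test_that("every analytic force matches the numerical gradient", {
  set.seed(42)
  nat <- make_toy_native("two_helix", 14, seed = 1)
  tun <- make_toy_tunnel(length = 30, radius = 8, seed = 2, check = FALSE)
  w <- wall_field(tun)
  w$mouth_xyz <- rbind(c(0, 0, 28), c(3, 0, 30))
  w$mouth_charge <- c(-1L, 1L)
  nat$charge <- rep(c(1L, -1L, 0L, 0L), length.out = 14)
  configs <- list(
    nat$xyz + matrix(rnorm(42, sd = 0.4), ncol = 3),          # near-native
    nat$xyz * 0.55 + matrix(rnorm(42, sd = 0.3), ncol = 3),   # compressed
    cbind(rnorm(14, sd = 3), rnorm(14, sd = 3), runif(14, 2, 28)))
  for (x in configs) {
    x[, 3] <- pmax(x[, 3], 1.5)
    for (fn in list(function(z) bonded_energy(z, nat, params),
                    function(z) contact_energy(z, nat, params),
                    function(z) wall_energy(z, w, params),
                    function(z) mouth_contacts(z, w, nat, params,
                                               enabled = TRUE))) {
      r <- fn(x)
      g <- num_grad(function(z) fn(z)$energy, x)
      expect_lt(max(abs(r$forces + g)), 1e-6)
    }
  }
})

test_that("mouth contacts: disabled term is zero, well minimum is -eps", {
  tun <- make_toy_tunnel(length = 30, radius = 8, seed = 2, check = FALSE)
  w <- wall_field(tun)
  w$mouth_xyz <- rbind(c(0, 0, 30))
  w$mouth_charge <- -1L
  nat <- native_model_from_ca(rbind(c(0, 0, 25), c(0, 0, 28.8)), cutoff = 0,
                              charge = c(1L, 0L))
  x <- rbind(c(0, 0, 25), c(0, 0, 28.8))
  expect_equal(mouth_contacts(x, w, nat, params, enabled = FALSE)$energy, 0)
  r <- mouth_contacts(x, w, nat, params, enabled = TRUE)
  expect_equal(r$energy, -1, tolerance = 1e-9)  # +1 bead 5 A from -1 residue
  # same-sign pair: no interaction
  w$mouth_charge <- 1L
  expect_equal(mouth_contacts(x, w, nat, params, enabled = TRUE)$energy, 0)
})

test_that("T = 0, gamma = 0 dynamics conserves energy", {
  dimer <- native_model_from_ca(rbind(c(0, 0, 10), c(0, 0, 13.8)),
                                cutoff = 0)
  p0 <- sim_params(temperature = 0, gamma = 0)
  tr <- run_trajectory(dimer, NULL, NULL, params = p0, t_E = 1e5 * p0$dt,
                       stride = 500, seed = 1,
                       x0 = rbind(c(0, 0, 10), c(0, 0, 13.81)))
  E <- tr$kinetic + tr$potential
  expect_lt(max(abs(E - E[1])), 1e-4)
})

test_that("thermostat reaches the target temperature within 3%", {
  nat <- make_toy_native("helix", 30, seed = 2)
  tr <- run_trajectory(nat, NULL, NULL, params = sim_params(), t_E = 2500,
                       stride = 10, seed = 3, x0 = nat$xyz)
  ke <- tr$kinetic[tr$times > 50]  # discard the cold start
  Tk <- mean(ke) / (0.5 * 3 * 30)
  expect_lt(abs(Tk - 0.35) / 0.35, 0.03)
})

test_that("identical seeds give bit-identical trajectories", {
  nat <- make_toy_native("hairpin", 12, seed = 1)
  tun <- make_toy_tunnel(length = 30, radius = 10, cap_top = FALSE,
                         seed = 3, check = FALSE)
  w <- wall_field(tun)
  a <- run_trajectory(nat, w, growth_schedule(12, 50), t_E = 800,
                      stride = 400, seed = 9)
  b <- run_trajectory(nat, w, growth_schedule(12, 50), t_E = 800,
                      stride = 400, seed = 9)
  expect_identical(a$frames, b$frames)
  expect_identical(a$events, b$events)
  c <- run_trajectory(nat, w, growth_schedule(12, 50), t_E = 800,
                      stride = 400, seed = 10)
  expect_false(identical(a$frames, c$frames))
})

test_that("growth schedules give the printed synthesis times", {
  # uniform: 56 residues at t_w = 100 -> released at 5600 tau
  s <- growth_schedule(56, 100)
  expect_equal(tail(s$release, 1), 5600)
  # two-segment schedule: 74 x 100 + 82 x 1000 = 89,400 tau
  s2 <- growth_schedule(156, data.frame(first = c(1, 75), last = c(74, 156),
                                        t_w = c(100, 1000)))
  expect_equal(tail(s2$release, 1), 74 * 100 + 82 * 1000)
  expect_equal(s2$birth[75], 7400)
  expect_error(growth_schedule(10, data.frame(first = c(1, 6), last = c(4, 10),
                                              t_w = c(10, 10))), "contiguous")
})

test_that("the event log realises the schedule exactly", {
  nat <- make_toy_native("hairpin", 10, seed = 1)
  tr <- run_trajectory(nat, wall_field(NULL, plate = TRUE),
                       growth_schedule(10, 40), t_E = 400, stride = 1000,
                       seed = 2)
  ev <- tidy(tr)
  births <- ev[ev$event == "birth", ]
  rel <- ev[ev$event == "release", ]
  expect_equal(births$time, (0:9) * 40)
  expect_equal(rel$time, (1:10) * 40)
  # t_E shorter than the first emergence interval: a single bead
  tr1 <- run_trajectory(nat, wall_field(NULL, plate = TRUE),
                        growth_schedule(10, 1000), t_E = 500, stride = 1000,
                        seed = 2)
  expect_equal(tr1$frames[[length(tr1$frames)]] |> nrow(), 1)
})

test_that("a two-helix hairpin folds off-ribosome at T = 0.35", {
  nat <- make_toy_native("two_helix", 20, seed = 1)
  x0 <- cbind(0, 0, seq_len(20) * 3.8)
  folded <- vapply(1:20, function(s) {
    tr <- run_trajectory(nat, NULL, NULL, params = sim_params(), t_E = 5e4,
                         stride = 5000, seed = s, x0 = x0,
                         stop_when_folded = TRUE)
    is.finite(tr$folding_time)
  }, logical(1))
  expect_gt(mean(folded), 0.5)
})
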