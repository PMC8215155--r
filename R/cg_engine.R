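# Coarse-grained structure-based Langevin engine: parameters, growth
# schedules, wall fields, energy terms and the trajectory driver.

#' Simulation parameters (reduced units)
#'
#' Energies are in units of the contact depth eps, lengths in Angstrom and
#' time in tau (~1 ns); k_B = 1 so temperature is in eps/k_B.
#'
#' @param epsilon contact well depth (the energy unit; default 1).
#' @param temperature in eps/k_B; the room-temperature default is 0.35.
#' @param dt integration timestep in tau (default 0.005).
#' @param gamma Langevin damping in 1/tau (default 2).
#' @param d0 Calpha-Calpha bond length in Angstrom (default 3.8).
#' @param k_bond harmonic bond stiffness in eps/A^2 (default 100).
#' @param kappa chirality stiffness in eps (default 1).
#' @param sigma0 repulsion length, 4 * 2^(-1/6) A, making the generic
#'   repulsion vanish smoothly at 4 A.
#' @param rep_cutoff generic repulsion cutoff in Angstrom (default 4).
#' @param wall_amp bottom-plate amplitude: the plate energy equals
#'   `wall_amp * epsilon` at z = sigma0 (default 332).
#' @param wall_exp bottom-plate exponent (default 9).
#' @param fold_mult a contact counts as formed when r < fold_mult * s_ij
#'   (default 1.5).
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(epsilon = 1, temperature = 0.35, dt = 0.005,
                       gamma = 2, d0 = 3.8, k_bond = 100, kappa = 1,
                       sigma0 = 4 * 2^(-1 / 6), rep_cutoff = 4,
                       wall_amp = 332, wall_exp = 9, fold_mult = 1.5) {
  stopifnot(dt > 0, temperature >= 0, gamma >= 0, d0 > 0, sigma0 > 0)
  structure(list(epsilon = epsilon, temperature = temperature, dt = dt,
                 gamma = gamma, d0 = d0, k_bond = k_bond, kappa = kappa,
                 sigma0 = sigma0, rep_cutoff = rep_cutoff,
                 wall_amp = wall_amp, wall_exp = wall_exp,
                 fold_mult = fold_mult),
            class = "sim_params")
}

#' Residue-emergence schedule for sequential growth at the PTC
#'
#' Residue k is born at the cumulative time of all earlier waiting intervals
#' and is fully released (its nascent bond ramped to full length, its
#' contacts eligible) one waiting interval t_w later, so a uniform schedule
#' of N residues at t_w finishes synthesis at exactly N * t_w.
#'
#' @param n chain length, used with a scalar `t_w` for a uniform schedule.
#' @param t_w waiting time per residue in tau, or a data frame with columns
#'   `first`, `last`, `t_w` giving contiguous segments covering 1..n.
#' @return a list of class `growth_schedule` with per-residue `birth`,
#'   `release` and `t_w` vectors.
#' @export
growth_schedule <- function(n, t_w = 100) {
  if (is.data.frame(t_w)) {
    seg <- t_w[order(t_w$first), , drop = FALSE]
    if (seg$first[1] != 1 || seg$last[nrow(seg)] != n ||
        (nrow(seg) > 1 && any(seg$first[-1] != head(seg$last, -1) + 1)))
      abort("segments must be contiguous and cover residues 1..n")
    tw <- unlist(lapply(seq_len(nrow(seg)), function(k)
      rep(seg$t_w[k], seg$last[k] - seg$first[k] + 1)))
  } else {
    tw <- rep(as.numeric(t_w), n)
  }
  if (any(tw <= 0)) abort("waiting times must be positive")
  release <- cumsum(tw)
  structure(list(birth = c(0, head(release, -1)), release = release,
                 t_w = tw, n = n),
            class = "growth_schedule")
}

#' @export
print.growth_schedule <- function(x, ...) {
  cat(sprintf("<growth_schedule> %d residues, synthesis complete at %g tau\n",
              x$n, tail(x$release, 1)))
  invisible(x)
}

#' Rigid wall field around the nascent chain
#'
#' Bundles the wall-atom coordinates of a cut-out (every atom a source of
#' the soft 4-A repulsion), the bottom-plate switch and the mouth plane,
#' plus - optionally - the charged mouth residues used by the
#' electrostatics-mimicking mouth contacts.
#'
#' @param cutout a `ribosome_cutout`, or NULL for off-ribosome simulations.
#' @param plate apply the bottom-plate potential (default TRUE when any wall
#'   geometry is present, FALSE off-ribosome unless requested).
#' @param mouth_z escape plane in Angstrom; default: the maximal wall-atom z.
#' @param mouth_region depth of the mouth region in Angstrom (wall residues
#'   with z within this distance of the top; default 10) used for mouth
#'   contacts.
#' @return a list of class `wall_field` (or NULL if `cutout` is NULL and
#'   `plate` is FALSE).
#' @export
wall_field <- function(cutout = NULL, plate = NULL, mouth_z = NULL,
                       mouth_region = 10) {
  if (is.null(cutout)) {
    plate <- isTRUE(plate)
    if (!plate) return(NULL)
    return(structure(list(coords = matrix(numeric(), 0, 3), plate = TRUE,
                          mouth_z = Inf, mouth_xyz = NULL,
                          mouth_charge = NULL),
                     class = "wall_field"))
  }
  stopifnot(inherits(cutout, "ribosome_cutout"))
  at <- cutout$atoms
  coords <- unname(cbind(at$x, at$y, at$z))
  zmax <- max(at$z)
  mouth_xyz <- NULL; mouth_charge <- NULL
  prot <- at[at$kind == "protein" & at$z >= zmax - mouth_region, ,
             drop = FALSE]
  if (nrow(prot)) {
    prot$q <- .residue_charge(prot$resname)
    ch <- prot[prot$q != 0, , drop = FALSE]
    if (nrow(ch)) {
      key <- paste(ch$chain, ch$resno)
      mouth_xyz <- do.call(rbind, lapply(split(seq_len(nrow(ch)), key),
        function(ix) colMeans(cbind(ch$x[ix], ch$y[ix], ch$z[ix]))))
      mouth_charge <- vapply(split(ch$q, key), function(q) q[1], integer(1))
      mouth_xyz <- unname(mouth_xyz)
      mouth_charge <- unname(mouth_charge)
    }
  }
  structure(list(coords = coords, plate = plate %||% TRUE,
                 mouth_z = mouth_z %||% zmax,
                 mouth_xyz = mouth_xyz, mouth_charge = mouth_charge),
            class = "wall_field")
}

.wall_list <- function(wall) {
  if (is.null(wall)) return(NULL)
  list(coords = wall$coords, plate = isTRUE(wall$plate),
       mouth_z = wall$mouth_z,
       mouth_xyz = wall$mouth_xyz,
       mouth_charge = wall$mouth_charge %||% integer())
}

.params_list <- function(params) unclass(params)

.energy_call <- function(x, native, params, wall, terms, bond_eq,
                         n_released) {
  .assert_matrix3(x, "x")
  cpp_energy_forces(x, unclass(native), .params_list(params),
                    .wall_list(wall), terms, bond_eq,
                    if (is.null(n_released)) -1L else as.integer(n_released))
}

#' Bonded energy and forces (harmonic bonds + chirality)
#'
#' Bonds contribute k (r - d_eq)^2; a quadratic chirality penalty of
#' stiffness kappa applies to every backbone quadruple whose chirality sign
#' disagrees with the native one. Forces are exact negative gradients.
#'
#' @param x n x 3 coordinates of the emerged beads.
#' @param native a `native_model`.
#' @param params a `sim_params`.
#' @param bond_eq optional per-bond equilibrium lengths (nascent-bond ramp);
#'   default d0 everywhere.
#' @return list with `energy` (eps), `forces` (n x 3, eps/A) and per-term
#'   breakdown.
#' @export
bonded_energy <- function(x, native, params = sim_params(), bond_eq = NULL) {
  r <- .energy_call(x, native, params, NULL, c("bond", "chirality"),
                    bond_eq, NULL)
  list(energy = r$energy, forces = r$forces, terms = r$terms)
}

#' Contact energy and forces (native wells + non-native repulsion)
#'
#' Native contacts of released pairs feel the 6-12 well of depth eps with
#' minimum at the native distance; all other non-bonded emerged pairs feel
#' the truncated-shifted 4-A repulsion. A contact is flagged formed when
#' r < fold_mult * s_ij.
#'
#' @inheritParams bonded_energy
#' @param n_released number of residues whose contacts are eligible
#'   (default: all rows of `x`).
#' @return list with `energy`, `forces`, per-contact `formed` flags and the
#'   per-term breakdown.
#' @export
contact_energy <- function(x, native, params = sim_params(),
                           n_released = NULL) {
  if (!nrow(native$contacts)) abort("native model has no contacts")
  r <- .energy_call(x, native, params, NULL, c("contacts", "nonnative"),
                    NULL, n_released)
  list(energy = r$energy, forces = r$forces, formed = r$formed,
       terms = r$terms)
}

#' Wall energy and forces (rigid wall atoms + bottom plate)
#'
#' Every wall atom within 4 A of a bead contributes the truncated-shifted
#' repulsion (amplitude eps at contact, zero at the cutoff); the bottom
#' plate contributes wall_amp * eps * (sigma0/z)^wall_exp per bead.
#'
#' @inheritParams bonded_energy
#' @param wall a `wall_field`.
#' @return list with `energy`, `forces` and the per-term breakdown.
#' @export
wall_energy <- function(x, wall, params = sim_params(),
                        native = NULL) {
  if (is.null(wall)) abort("`wall` is NULL")
  native <- native %||% native_model_from_ca(
    cbind(0, 0, seq_len(nrow(x)) * 3.8), cutoff = 0)
  if (any(x[, 3] <= 0) && isTRUE(wall$plate))
    abort("bead z <= 0: wall penetration")
  r <- .energy_call(x, native, params, wall, c("wall_atoms", "plate"),
                    NULL, NULL)
  list(energy = r$energy, forces = r$forces, terms = r$terms)
}

#' Electrostatics-mimicking mouth contacts (disabled by default)
#'
#' Attractive eps-deep wells (minimum at 5 A) between charged nascent-chain
#' beads and oppositely charged wall residues in the mouth region. The
#' production setup runs without them.
#'
#' @inheritParams wall_energy
#' @param enabled logical switch; when FALSE the term is identically zero.
#' @return list with `energy` and `forces`.
#' @export
mouth_contacts <- function(x, wall, native, params = sim_params(),
                           enabled = FALSE) {
  if (!enabled || is.null(wall) || is.null(wall$mouth_xyz)) {
    return(list(energy = 0, forces = matrix(0, nrow(x), 3)))
  }
  r <- .energy_call(x, native, params, wall, "mouth", NULL, NULL)
  list(energy = r$energy, forces = r$forces)
}

#' One-call Langevin step (exposed mainly for unit checks)
#'
#' Advances a bare chain by `n_steps` BAOAB Langevin steps under the full
#' off-ribosome potential and returns positions, velocities and the energy
#' series. [run_trajectory()] is the production driver.
#'
#' @param x,v initial positions and velocities (n x 3).
#' @param native a `native_model`.
#' @param params a `sim_params`.
#' @param n_steps number of steps.
#' @param seed RNG seed.
#' @param wall optional `wall_field`.
#' @param stride recording stride in steps.
#' @return a `cg_trajectory`.
#' @export
step_langevin <- function(x, v = NULL, native, params = sim_params(),
                          n_steps = 1, seed = 1, wall = NULL,
                          stride = 1) {
  run_trajectory(native, wall = wall, schedule = NULL, params = params,
                 t_E = n_steps * params$dt, stride = stride, seed = seed,
                 x0 = x, v0 = v)
}

#' Run a growth-and-folding trajectory
#'
#' Integrates the nascent chain with BAOAB Langevin dynamics to time `t_E`,
#' growing residues at the PTC according to `schedule` (each new bead
#' appears just above the PTC with a seeded lateral jitter; its bond to the
#' previous bead ramps linearly from zero to d0 over the residue's waiting
#' interval - the quasi-continuous growth). Frames are recorded every
#' `stride` steps together with an event log (birth, release, folded,
#' escape). Fully reproducible from `seed`.
#'
#' @param native a `native_model`.
#' @param wall a `wall_field` or NULL (off-ribosome).
#' @param schedule a `growth_schedule`, or NULL when `x0` is supplied.
#' @param params a `sim_params`.
#' @param t_E total simulated time in tau.
#' @param stride frame-recording stride in steps.
#' @param seed integer RNG seed.
#' @param x0,v0 optional pre-built chain (disables growth; all contacts
#'   eligible from t = 0).
#' @param mouth enable the electrostatics-mimicking mouth contacts.
#' @param z_emerge emergence height above the PTC plane in Angstrom.
#' @param emerge_jitter lateral emergence jitter (standard deviation, A).
#' @param check_every event-check interval in steps.
#' @param stop_when_folded,stop_when_escaped end the run early at the event.
#' @return an object of class `cg_trajectory`.
#' @export
run_trajectory <- function(native, wall = NULL, schedule = NULL,
                           params = sim_params(), t_E, stride = 1000,
                           seed = 1, x0 = NULL, v0 = NULL, mouth = FALSE,
                           z_emerge = 5, emerge_jitter = 0.05,
                           check_every = 50, stop_when_folded = FALSE,
                           stop_when_escaped = FALSE) {
  stopifnot(inherits(native, "native_model"), t_E > 0)
  if (is.null(x0) && is.null(schedule))
    abort("supply either a growth schedule or initial coordinates x0")
  if (!is.null(schedule) && is.null(x0) &&
      schedule$n != length(native$sequence))
    abort("schedule length does not match the native model")
  sched <- if (is.null(schedule))
    list(birth = numeric(), release = numeric(), t_w = numeric())
  else unclass(schedule)
  res <- cpp_run_trajectory(
    unclass(native), .params_list(params), .wall_list(wall), sched,
    as.numeric(t_E), as.integer(stride), as.integer(seed),
    x0, v0, isTRUE(mouth), z_emerge, emerge_jitter,
    as.integer(check_every), isTRUE(stop_when_folded),
    isTRUE(stop_when_escaped))
  structure(list(
    times = res$times, frames = res$frames,
    n_emerged = res$n_emerged, kinetic = res$kinetic,
    potential = res$potential,
    events = as_tibble(res$events),
    folding_time = res$folding_time, escape_time = res$escape_time,
    formed = res$formed, t_end = res$t_end, n_res = length(native$sequence),
    seed = seed, params = params,
    mouth_z = if (!is.null(wall)) wall$mouth_z else Inf,
    digest = rlang::hash(list(unclass(native), unclass(params), sched,
                              t_E, seed))),
    class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cg_trajectory> %d residues, %d frames to t = %g tau (seed %d)\n",
    x$n_res, length(x$times), x$t_end, x$seed))
  if (is.finite(x$folding_time %||% NA))
    cat(sprintf("  folded at %g tau\n", x$folding_time))
  if (is.finite(x$escape_time %||% NA))
    cat(sprintf("  escaped at %g tau\n", x$escape_time))
  invisible(x)
}

#' @rdname tidy-ribotunnel
#' @export
tidy.cg_trajectory <- function(x, ...) as_tibble(x$events)

#' @rdname glance-ribotunnel
#' @export
glance.cg_trajectory <- function(x, ...) {
  tibble(n_res = x$n_res, n_frames = length(x$times), t_end = x$t_end,
         folding_time = x$folding_time, escape_time = x$escape_time,
         seed = x$seed)
}

#' Write trajectory frames in multi-frame XYZ text format
#'
#' @param traj a `cg_trajectory`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(traj$frames)) {
    fx <- traj$frames[[k]]
    writeLines(c(sprintf("%d", nrow(fx)),
                 sprintf("t= %.6f", traj$times[k]),
                 sprintf("CA %.4f %.4f %.4f", fx[, 1], fx[, 2], fx[, 3])),
               con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file back into frames
#'
#' @param path XYZ file written by [write_trajectory_xyz()].
#' @return list with `times` and `frames`.
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  times <- numeric(); frames <- list(); k <- 1L
  while (k <= length(lines)) {
    n <- as.integer(lines[k])
    t <- as.numeric(sub("t= *", "", lines[k + 1L]))
    block <- lines[(k + 2L):(k + 1L + n)]
    m <- do.call(rbind, lapply(strsplit(block, " +"), function(f)
      as.numeric(f[2:4])))
    times <- c(times, t)
    frames[[length(frames) + 1L]] <- m
    k <- k + 2L + n
  }
  list(times = times, frames = frames)
}
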