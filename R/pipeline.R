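# Orchestration: geometry -> simulation -> analysis with a YAML run
# configuration, reproducible per-trajectory seeds and resumable run
# directories.

#' Read (or normalise) a run configuration
#'
#' The configuration is a YAML file (or an equivalent nested list) with
#' blocks `ribosome` (a `path` to a tunnel-frame PDB fragment, a `frame`
#' for raw structures, or a `toy` tunnel spec), `native` (a `path` or a
#' `toy` model spec), `geometry`, `params`, `growth` and `simulate`.
#' Unset fields take the package defaults.
#'
#' @param config path to a YAML file, or a list.
#' @return a list of class `run_config` with a `digest` attribute.
#' @export
run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  # YAML 1.1 parses a bare `n:` key as a boolean; the only such key in the
  # configuration schema is the residue count, so map it back
  fix_keys <- function(x) {
    if (is.data.frame(x) || !is.list(x)) return(x)
    names(x)[names(x) %in% c("FALSE", "no")] <- "n"
    lapply(x, fix_keys)
  }
  cfg <- fix_keys(cfg)
  cfg$geometry <- utils::modifyList(
    list(spacing = 1, probe_radii = c(4, 3), rotations = 10, bin_width = 2,
         seed = 1), cfg$geometry %||% list())
  cfg$simulate <- utils::modifyList(
    list(t_E = 10000, stride = 1000, ensemble = 5, seed_base = 1,
         mouth = FALSE, t_check = NULL), cfg$simulate %||% list())
  cfg$params <- do.call(sim_params, cfg$params %||% list())
  cfg$growth <- cfg$growth %||% list(t_w = 100)
  attr(cfg, "digest") <- rlang::hash(cfg)
  structure(cfg, class = c("run_config", "list"))
}

.cfg_cutout <- function(cfg) {
  rb <- cfg$ribosome
  if (!is.null(rb$toy)) return(do.call(make_toy_tunnel, rb$toy))
  if (is.null(rb$path)) abort("config: ribosome needs a `path` or a `toy` spec")
  atoms <- load_structure(rb$path)
  if (isTRUE(rb$in_tunnel_frame) || is.null(rb$frame)) {
    fr <- tunnel_frame(c(0, 0, 0), c(0, 0, 1), rb$radius %||% 70)
    return(structure(list(atoms = atoms, n_kept = nrow(atoms),
                          n_total = nrow(atoms), frame = fr),
                     class = "ribosome_cutout"))
  }
  fr <- tunnel_frame(rb$frame$origin, rb$frame$axis, rb$frame$radius %||% 70)
  extract_cutout(atoms, fr)
}

.cfg_native <- function(cfg) {
  nt <- cfg$native
  if (!is.null(nt$toy)) return(do.call(make_toy_native, nt$toy))
  if (is.null(nt$path)) abort("config: native needs a `path` or a `toy` spec")
  build_native_model(nt$path, chain = nt$chain,
                     scale = nt$scale %||% 1.24,
                     min_sep = nt$min_sep %||% 3)
}

.write_meta <- function(cfg, dir, extra = list()) {
  meta <- c(list(digest = attr(cfg, "digest"),
                 version = as.character(utils::packageVersion("ribotunnel"))),
            extra)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
}

#' Geometry stage: cut-out, cavity, volumes, profile, constrictions
#'
#' @param config a `run_config` (or something [run_config()] accepts).
#' @param outdir output directory (created).
#' @return invisibly, a list with the cavity maps, volume table, profile
#'   and constriction table.
#' @export
run_geometry <- function(config, outdir) {
  cfg <- run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cutout <- .cfg_cutout(cfg)
  write_cutout_pdb(cutout, file.path(outdir, "cutout.pdb"))
  vols <- list(); cavs <- list()
  for (p in cfg$geometry$probe_radii) {
    g <- rasterize(cutout, spacing = cfg$geometry$spacing, probe_radius = p)
    cav <- probe_accessibility(g, rotations = cfg$geometry$rotations,
                               seed = cfg$geometry$seed)
    v <- tunnel_volume(cav)
    v$surface_to_volume <- surface_to_volume(cav)
    vols[[as.character(p)]] <- v
    cavs[[as.character(p)]] <- cav
  }
  vol_tab <- dplyr::bind_rows(vols)
  utils::write.csv(vol_tab, file.path(outdir, "volumes.csv"),
                   row.names = FALSE)
  cav1 <- cavs[[1]]
  write_cavity_pdb(cav1, file.path(outdir, "cavity.pdb"))
  write_cavity_grid(cav1, file.path(outdir, "cavity.dx"))
  prof <- axial_profile(cav1, bin_width = cfg$geometry$bin_width)
  utils::write.csv(prof, file.path(outdir, "profile.csv"), row.names = FALSE)
  cons <- find_constrictions(prof)
  utils::write.csv(cons, file.path(outdir, "constrictions.csv"),
                   row.names = FALSE)
  .write_meta(cfg, outdir, list(stage = "geometry"))
  invisible(list(cutout = cutout, cavities = cavs, volumes = vol_tab,
                 profile = prof, constrictions = cons))
}

#' Simulation stage: a seeded, resumable trajectory ensemble
#'
#' Trajectory k runs with seed `seed_base + k - 1` in its own
#' subdirectory; completed trajectories (marked by a `done` file) are not
#' recomputed on resume.
#'
#' @param config a `run_config`.
#' @param outdir output directory.
#' @return invisibly, the vector of trajectory directories.
#' @export
run_simulation <- function(config, outdir) {
  cfg <- run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  native <- .cfg_native(cfg)
  wall <- if (is.null(cfg$ribosome)) wall_field(NULL, plate = TRUE)
    else wall_field(.cfg_cutout(cfg))
  n <- length(native$sequence)
  sched <- if (!is.null(cfg$growth$segments))
    growth_schedule(n, as.data.frame(dplyr::bind_rows(cfg$growth$segments)))
  else growth_schedule(n, cfg$growth$t_w)
  dirs <- character(cfg$simulate$ensemble)
  for (k in seq_len(cfg$simulate$ensemble)) {
    td <- file.path(outdir, sprintf("traj_%03d", k))
    dirs[k] <- td
    if (file.exists(file.path(td, "done"))) next
    dir.create(td, recursive = TRUE, showWarnings = FALSE)
    seed <- cfg$simulate$seed_base + k - 1
    traj <- tryCatch(
      run_trajectory(native, wall = wall, schedule = sched,
                     params = cfg$params, t_E = cfg$simulate$t_E,
                     stride = cfg$simulate$stride, seed = seed,
                     mouth = isTRUE(cfg$simulate$mouth)),
      error = function(e) e)
    if (inherits(traj, "error")) {
      writeLines(conditionMessage(traj), file.path(td, "failed"))
      next
    }
    write_trajectory_xyz(traj, file.path(td, "frames.xyz"))
    utils::write.table(traj$events, file.path(td, "events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(list(seed = seed, t_end = traj$t_end,
                          n_res = traj$n_res,
                          mouth_z = if (is.finite(traj$mouth_z))
                            traj$mouth_z else "inf",
                          folding_time = traj$folding_time,
                          escape_time = traj$escape_time),
                     file.path(td, "summary.yaml"))
    file.create(file.path(td, "done"))
  }
  .write_meta(cfg, outdir, list(stage = "simulate"))
  invisible(dirs)
}

.read_traj_dir <- function(td) {
  xyz <- read_trajectory_xyz(file.path(td, "frames.xyz"))
  ev <- as_tibble(utils::read.table(file.path(td, "events.tsv"),
                                    header = TRUE, sep = "\t"))
  sm <- yaml::read_yaml(file.path(td, "summary.yaml"))
  structure(list(
    times = xyz$times, frames = xyz$frames, events = ev,
    folding_time = sm$folding_time %||% NA_real_,
    escape_time = sm$escape_time %||% NA_real_,
    t_end = sm$t_end, n_res = sm$n_res,
    mouth_z = if (identical(sm$mouth_z, "inf")) Inf else sm$mouth_z,
    seed = sm$seed),
    class = "cg_trajectory")
}

#' Analysis stage: outcomes, histogram, folding times, knots, report
#'
#' @param config a `run_config`.
#' @param simdir directory written by [run_simulation()].
#' @param geodir directory written by [run_geometry()] (for the profile);
#'   NULL uses explicit `cs`/`mouth_z`.
#' @param outdir output directory (default `simdir`).
#' @param cs,mouth_z optional explicit constriction positions/mouth plane.
#' @return invisibly, a list with outcomes, histogram and the
#'   `ensemble_report`.
#' @export
run_analysis <- function(config, simdir, geodir = NULL, outdir = simdir,
                         cs = NULL, mouth_z = NULL) {
  cfg <- run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tds <- list.dirs(simdir, recursive = FALSE)
  tds <- tds[file.exists(file.path(tds, "done"))]
  if (!length(tds)) abort("no completed trajectories found")
  if (!is.null(geodir)) {
    cons <- utils::read.csv(file.path(geodir, "constrictions.csv"))
    prof <- utils::read.csv(file.path(geodir, "profile.csv"))
    cs <- cs %||% cons$z
    mouth_z <- mouth_z %||% max(prof$z[prof$area > 0])
  }
  if (is.null(cs)) abort("supply geodir or explicit cs positions")
  trajs <- lapply(tds, .read_traj_dir)
  summaries <- dplyr::bind_rows(lapply(trajs, classify_outcome, cs = cs,
                                       mouth_z = mouth_z,
                                       t_check = cfg$simulate$t_check))
  summaries$trajectory <- basename(tds)
  knots <- lapply(trajs, function(tr) {
    fx <- tr$frames[[length(tr$frames)]]
    if (nrow(fx) >= 3) knot_type(fx, seed = tr$seed)
    else list(type = "unknot", determinant = 1)
  })
  knot_tab <- tibble(trajectory = basename(tds),
                     knot_type = vapply(knots, function(k) k$type,
                                        character(1)),
                     determinant = vapply(knots, function(k)
                       as.numeric(k$determinant), numeric(1)))
  hist <- outcome_histogram(summaries, cs = cs, mouth_z = mouth_z)
  rep <- ensemble_report(summaries, knots)
  utils::write.csv(summaries, file.path(outdir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(hist, file.path(outdir, "histogram.csv"),
                   row.names = FALSE)
  utils::write.csv(knot_tab, file.path(outdir, "knots.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$stats, file.path(outdir, "report.csv"),
                   row.names = FALSE)
  .write_meta(cfg, outdir, list(stage = "analyze"))
  invisible(list(outcomes = summaries, histogram = hist, knots = knot_tab,
                 report = rep))
}
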