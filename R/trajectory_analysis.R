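# Trajectory observables: termini distances, trapping/escape
# classification against the constriction sites, folding detection, and
# ensemble aggregation.

#' Distances of the chain termini from the PTC over time
#'
#' @param traj a `cg_trajectory` (or a list with `times` and `frames`).
#' @return a tibble with columns `t`, `d_N`, `d_C` (Angstrom; the N-terminus
#'   is bead 1, the C-terminus the last emerged bead).
#' @export
termini_distance <- function(traj) {
  if (!length(traj$frames)) abort("trajectory has no frames")
  dN <- vapply(traj$frames, function(f)
    if (nrow(f)) sqrt(sum(f[1, ]^2)) else NA_real_, numeric(1))
  dC <- vapply(traj$frames, function(f)
    if (nrow(f)) sqrt(sum(f[nrow(f), ]^2)) else NA_real_, numeric(1))
  tibble(t = traj$times, d_N = dN, d_C = dC)
}

.cs_positions <- function(profile = NULL, cs = NULL) {
  if (!is.null(cs)) return(as.numeric(cs))
  if (is.null(profile)) abort("supply a tunnel profile or cs positions")
  con <- find_constrictions(profile)
  con$z
}

#' Classify a trajectory outcome against the constriction sites
#'
#' ESCAPED when every bead's axial coordinate passed the mouth plane at or
#' before `t_check`; otherwise the trajectory is labelled by where the
#' N-terminus sits at `t_check`: below CS1 (STUCK_PTC_CS1), between CS1 and
#' CS2 (STUCK_CS1_CS2), or beyond CS2 but still inside (STUCK_CS2_MOUTH).
#'
#' @param traj a `cg_trajectory`.
#' @param profile a `tunnel_profile` used to locate CS1/CS2 and the mouth
#'   plane, or NULL when `cs` and `mouth_z` are given.
#' @param cs optional numeric vector of constriction z positions.
#' @param mouth_z escape plane; default: the trajectory's wall mouth, else
#'   the last profile bin with positive area.
#' @param t_check classification time in tau (default: end of trajectory).
#' @return a one-row tibble with `label`, `z_N`, `d_N`, `escape_time`,
#'   `folding_time`.
#' @export
classify_outcome <- function(traj, profile = NULL, cs = NULL,
                             mouth_z = NULL, t_check = NULL) {
  t_check <- t_check %||% traj$t_end
  if (t_check > traj$t_end + 1e-9)
    abort("t_check exceeds the trajectory end")
  zcs <- .cs_positions(profile, cs)
  mouth_z <- mouth_z %||%
    (if (is.finite(traj$mouth_z %||% Inf)) traj$mouth_z
     else if (!is.null(profile)) max(profile$z[profile$area > 0])
     else abort("supply mouth_z"))
  k <- max(which(traj$times <= t_check + 1e-9))
  fx <- traj$frames[[k]]
  zN <- fx[1, 3]
  dN <- sqrt(sum(fx[1, ]^2))
  esc <- traj$escape_time
  escaped <- is.finite(esc %||% NA) && esc <= t_check + 1e-9
  if (!escaped && all(fx[, 3] > mouth_z)) {
    escaped <- TRUE
    esc <- traj$times[k]
  }
  label <- if (escaped) "ESCAPED"
  else if (!length(zcs) || zN <= zcs[1]) "STUCK_PTC_CS1"
  else if (length(zcs) >= 2 && zN <= zcs[2]) "STUCK_CS1_CS2"
  else "STUCK_CS2_MOUTH"
  tibble(label = label, z_N = zN, d_N = dN,
         escape_time = if (escaped) esc else NA_real_,
         folding_time = traj$folding_time %||% NA_real_)
}

#' First time at which every native contact is formed
#'
#' Scans recorded frames (all residues present) and returns the first frame
#' time with every native-contact Calpha distance below `mult * s_ij`,
#' where s_ij = r_nat * 2^(-1/6); NA when folding is never observed. The
#' resolution is the recording stride.
#'
#' @param traj a `cg_trajectory`.
#' @param native the `native_model` that was simulated.
#' @param params a `sim_params` (supplies the default threshold multiplier).
#' @param mult threshold multiplier (default `params$fold_mult`).
#' @return folding time in tau, or NA.
#' @export
folding_time <- function(traj, native, params = sim_params(), mult = NULL) {
  mult <- mult %||% params$fold_mult
  con <- native$contacts
  if (!nrow(con)) abort("native model has no contacts")
  thr <- mult * con$r_nat * 2^(-1 / 6)
  n <- length(native$sequence)
  for (k in seq_along(traj$frames)) {
    fx <- traj$frames[[k]]
    if (nrow(fx) < n) next
    d <- sqrt((fx[con$i, 1] - fx[con$j, 1])^2 +
              (fx[con$i, 2] - fx[con$j, 2])^2 +
              (fx[con$i, 3] - fx[con$j, 3])^2)
    if (all(d < thr)) return(traj$times[k])
  }
  NA_real_
}

#' Aggregate an ensemble of trajectory outcomes
#'
#' @param summaries a tibble of rows from [classify_outcome()].
#' @param knots optional list of `knot_report`s (one per trajectory).
#' @param boot bootstrap replicates for the folding-time intervals.
#' @param seed bootstrap seed.
#' @return a list of class `ensemble_report` with `$fractions` (per-label
#'   counts and fractions), `$stats` (escape/folded/knotted fractions,
#'   folding-time median and mean with percentile bootstrap intervals) and
#'   `$n`.
#' @export
ensemble_report <- function(summaries, knots = NULL, boot = 200, seed = 1) {
  if (!nrow(summaries)) abort("no trajectories to aggregate")
  n <- nrow(summaries)
  lev <- c("STUCK_PTC_CS1", "STUCK_CS1_CS2", "STUCK_CS2_MOUTH", "ESCAPED")
  counts <- table(factor(summaries$label, levels = lev))
  fractions <- tibble(label = names(counts),
                      count = as.integer(counts),
                      fraction = as.numeric(counts) / n)
  ft <- summaries$folding_time[is.finite(summaries$folding_time)]
  knotted <- if (is.null(knots)) NA_real_
    else mean(vapply(knots, function(k) !identical(k$type, "unknot"),
                     logical(1)))
  ci <- c(NA_real_, NA_real_)
  if (length(ft) >= 2) {
    set.seed(seed)
    meds <- replicate(boot, median(sample(ft, replace = TRUE)))
    ci <- unname(quantile(meds, c(0.025, 0.975)))
  }
  stats <- tibble(
    n = n,
    escape_fraction = mean(summaries$label == "ESCAPED"),
    folded_fraction = mean(is.finite(summaries$folding_time)),
    knotted_fraction = knotted,
    folding_time_median = if (length(ft)) median(ft) else NA_real_,
    folding_time_mean = if (length(ft)) mean(ft) else NA_real_,
    folding_time_ci_lo = ci[1], folding_time_ci_hi = ci[2])
  structure(list(fractions = fractions, stats = stats, n = n),
            class = "ensemble_report")
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat(sprintf("<ensemble_report> %d trajectories\n", x$n))
  print(x$fractions)
  print(x$stats)
  invisible(x)
}

#' Histogram of final N-terminus distances in constriction-site binning
#'
#' Bin edges follow the trapping analysis: 0 to CS1, CS1 to CS2, then
#' uniform 10-A bins up to the mouth plane.
#'
#' @param summaries tibble of rows from [classify_outcome()].
#' @param cs numeric vector of constriction z positions (>= 1).
#' @param mouth_z mouth plane (Angstrom).
#' @return a tibble with `bin`, `lo`, `hi`, `count`.
#' @export
outcome_histogram <- function(summaries, cs = numeric(), mouth_z) {
  edges <- c(0, cs[seq_len(min(2, length(cs)))])  # 0 | CS1 | CS2 if present
  top <- max(mouth_z, max(summaries$d_N))
  edges <- c(edges, seq(tail(edges, 1) + 10, top + 10, by = 10))
  counts <- table(cut(summaries$d_N, edges, include.lowest = TRUE))
  tibble(bin = seq_along(counts),
         lo = head(edges, -1), hi = edges[-1],
         count = as.integer(counts))
}
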