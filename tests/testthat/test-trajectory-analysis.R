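# termini series, outcome classification, folding detection, ensembles

make_frozen_traj <- function(frames, times = seq_along(frames) * 10,
                             mouth_z = 30, escape_time = NA_real_,
                             folding_time = NA_real_) {
  structure(list(times = times, frames = frames,
                 events = tibble::tibble(event = character(),
                                         time = numeric(),
                                         residue = integer()),
                 folding_time = folding_time, escape_time = escape_time,
                 t_end = max(times), n_res = nrow(frames[[1]]),
                 mouth_z = mouth_z, seed = 1),
            class = "cg_trajectory")
}

test_that("termini distances are plain Euclidean distances from the PTC", {
  tr <- make_frozen_traj(list(rbind(c(0, 0, 0)),
                              rbind(c(3, 4, 0), c(0, 0, 12))))
  td <- termini_distance(tr)
  expect_equal(td$d_N, c(0, 5))
  expect_equal(td$d_C, c(0, 12))
  # a real run recomputes to the same values frame by frame
  nat <- make_toy_native("hairpin", 10, seed = 1)
  run <- run_trajectory(nat, wall_field(NULL, plate = TRUE),
                        growth_schedule(10, 30), t_E = 400, stride = 500,
                        seed = 4)
  td2 <- termini_distance(run)
  manual <- vapply(run$frames, function(f) sqrt(sum(f[1, ]^2)), numeric(1))
  expect_equal(td2$d_N, manual)
})

test_that("outcomes are classified against CS1/CS2 and the mouth plane", {
  below_cs1 <- make_frozen_traj(list(rbind(c(0, 0, 10), c(0, 0, 14))))
  mid <- make_frozen_traj(list(rbind(c(0, 0, 40), c(0, 0, 36))))
  out <- make_frozen_traj(list(rbind(c(0, 0, 31), c(0, 0, 33))))
  cs <- c(30, 50)
  expect_identical(classify_outcome(below_cs1, cs = cs, mouth_z = 60)$label,
                   "STUCK_PTC_CS1")
  expect_identical(classify_outcome(mid, cs = cs, mouth_z = 60)$label,
                   "STUCK_CS1_CS2")
  # every bead beyond the mouth plane: escaped
  expect_identical(classify_outcome(out, cs = cs, mouth_z = 30)$label,
                   "ESCAPED")
  expect_error(classify_outcome(below_cs1, cs = cs, mouth_z = 60,
                                t_check = 999), "t_check")
})

test_that("ensemble fractions equal direct counts and are exchangeable", {
  labs <- c(rep("STUCK_PTC_CS1", 5), rep("STUCK_CS1_CS2", 3),
            rep("ESCAPED", 2))
  summaries <- tibble::tibble(
    label = labs, z_N = 10, d_N = c(5, 8, 11, 14, 17, 35, 38, 41, 70, 75),
    escape_time = ifelse(labs == "ESCAPED", 100, NA_real_),
    folding_time = c(rep(NA_real_, 8), 120, 150))
  rep1 <- ensemble_report(summaries)
  expect_equal(rep1$stats$escape_fraction, 0.2)
  expect_equal(rep1$stats$folded_fraction, 0.2)
  expect_equal(rep1$fractions$count[rep1$fractions$label == "STUCK_PTC_CS1"],
               5L)
  set.seed(1)
  perm <- summaries[sample(nrow(summaries)), ]
  rep2 <- ensemble_report(perm)
  expect_equal(rep1$fractions, rep2$fractions)
  # all-escaped ensemble
  all_esc <- summaries
  all_esc$label <- "ESCAPED"
  expect_equal(ensemble_report(all_esc)$stats$escape_fraction, 1)
  # histogram equals direct counting in the CS binning
  h <- outcome_histogram(summaries, cs = c(30, 50), mouth_z = 70)
  expect_equal(sum(h$count), nrow(summaries))
  expect_equal(h$count[1], sum(summaries$d_N <= 30))
})

test_that("knotted fraction counts non-trivial final-frame knots", {
  knots <- list(knot_type(make_knot_curve("trefoil", 100, tail = 10)),
                knot_type(make_knot_curve("unknot", 80)),
                knot_type(cbind(0, 0, 1:10)))
  summaries <- tibble::tibble(label = rep("ESCAPED", 3), z_N = 1, d_N = 1,
                              escape_time = 1, folding_time = NA_real_)
  rep <- ensemble_report(summaries, knots)
  expect_equal(rep$stats$knotted_fraction, 1 / 3)
  expect_equal(ensemble_report(summaries, list())$stats$knotted_fraction,
               NaN)
})

test_that("folding time is the first frame with all contacts formed", {
  nat <- make_toy_native("hairpin", 10, seed = 1)
  ext <- cbind(0, 0, seq_len(10) * 3.8)
  # frozen in the native state from t = 0: folding time = first frame
  frozen <- make_frozen_traj(list(nat$xyz, nat$xyz), times = c(5, 10))
  expect_equal(folding_time(frozen, nat), 5)
  # fully extended forever: never folds
  never <- make_frozen_traj(list(ext, ext), times = c(5, 10))
  expect_true(is.na(folding_time(never, nat)))
  # folding at a later frame is found by the scan, and matches brute force
  mix <- make_frozen_traj(list(ext, ext, nat$xyz, nat$xyz),
                          times = c(1, 2, 3, 4))
  expect_equal(folding_time(mix, nat), 3)
  # monotone in the threshold multiplier
  nearly <- nat$xyz * 1.12
  tr <- make_frozen_traj(list(ext, nearly, nat$xyz), times = 1:3)
  t_tight <- folding_time(tr, nat, mult = 1.2)
  t_loose <- folding_time(tr, nat, mult = 1.6)
  expect_true(is.na(t_tight) || t_loose <= t_tight)
  expect_lte(folding_time(tr, nat, mult = 2), folding_time(tr, nat, mult = 1.5))
})

test_that("an engine folding event matches the frame-scan oracle", {
  nat <- make_toy_native("hairpin", 12, seed = 1)
  x0 <- cbind(0, 0, seq_len(12) * 3.8)
  tr <- run_trajectory(nat, NULL, NULL, params = sim_params(), t_E = 2e4,
                       stride = 200, seed = 6, x0 = x0)
  ft <- folding_time(tr, nat)
  if (is.finite(ft)) {
    con <- nat$contacts
    thr <- 1.5 * con$r_nat * 2^(-1 / 6)
    ok <- vapply(tr$frames, function(f) {
      d <- sqrt(rowSums((f[con$i, , drop = FALSE] -
                           f[con$j, , drop = FALSE])^2))
      all(d < thr)
    }, logical(1))
    expect_equal(ft, tr$times[which(ok)[1]])
  } else {
    succeed("no folding within the short window; nothing to cross-check")
  }
})
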