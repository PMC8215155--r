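# KMT reduction and Alexander-determinant knot typing

test_that("straight lines and planar zigzags reduce to their endpoints", {
  straight <- cbind(seq(0, 99), 0, 0)
  expect_equal(nrow(kmt_reduce(straight)), 2)
  zigzag <- cbind(seq(0, 49), rep(c(0, 3), 25), 0)
  expect_equal(nrow(kmt_reduce(zigzag)), 2)
})

test_that("KMT reduction preserves the Alexander determinant", {
  for (kind in c("trefoil", "figure_eight")) {
    curve <- make_knot_curve(kind, 200)
    red <- kmt_reduce(curve)
    expect_lt(nrow(red), 20)
    expect_equal(knot_type(red, seed = 2)$determinant,
                 knot_type(curve, seed = 2)$determinant)
  }
})

test_that("parametric curves are typed by their textbook determinants", {
  expect_identical(knot_type(make_knot_curve("trefoil", 120, tail = 20))$type,
                   "trefoil")
  expect_equal(knot_type(make_knot_curve("trefoil", 120))$determinant, 3)
  f8 <- knot_type(make_knot_curve("figure_eight", 150))
  expect_identical(f8$type, "other(5)")
  expect_equal(f8$determinant, 5)
  expect_identical(knot_type(make_knot_curve("unknot", 80))$type, "unknot")
  expect_identical(knot_type(cbind(0, 0, seq(0, 20)))$type, "unknot")
  # closed (2,3) torus curve without closure machinery
  expect_equal(knot_type(closed_trefoil(120), closed = TRUE)$determinant, 3)
})

test_that("knot type is invariant under rigid motion and scaling", {
  curve <- make_knot_curve("trefoil", 100, tail = 10)
  set.seed(11)
  R <- ribotunnel:::.random_rotation()
  moved <- curve %*% t(R) * 2.7
  moved <- sweep(moved, 2, c(15, -40, 3), FUN = "+")
  expect_identical(knot_type(moved, seed = 5)$type, "trefoil")
  expect_identical(knot_type(curve / 10, seed = 5)$type, "trefoil")
})

test_that("short self-avoiding walks are almost surely unknotted", {
  dets <- vapply(1:200, function(s)
    knot_type(sa_walk(30, seed = s), seed = s)$determinant, numeric(1))
  expect_gte(mean(dets == 1), 0.99)
})

test_that("knot core of a deep trefoil lands inside the knotted segment", {
  # straight tail + trefoil + straight tail: core must sit in the middle
  core_curve <- make_knot_curve("trefoil", 80, tail = 20)
  n <- nrow(core_curve)
  kc <- knot_core(core_curve)
  expect_identical(kc$type, "trefoil")
  expect_gte(kc$core[1], 21 - 2)
  expect_lte(kc$core[2], (n - 20) + 2)
  # the core is itself a bounded, knotted sub-chain
  expect_gt(kc$core[2] - kc$core[1], 10)
  # an unknotted chain reports no core
  expect_null(knot_core(make_knot_curve("unknot", 80))$core)
})
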