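# Seeded generators of synthetic tunnels, toy native models and parametric
# knotted curves, so every stage runs with no structure downloads. The
# generators emit the same containers as the production path (a
# ribosome_cutout of pseudo-atoms, a native_model), making them drop-in
# replacements for real inputs.

#' Synthetic exit tunnel of pseudo-atoms
#'
#' Builds a cylindrical wall of pseudo-atoms (vdW radius 1.7 A) on a
#' jittered lattice realising a piecewise inner-radius profile r(z): a base
#' radius modulated by Gaussian waists. The PTC sits at the origin with the
#' axis along +z. Walls extend `end_margin` beyond both ends; caps close
#' them off (a closed lumen measures cleanly; open the top for growth
#' simulations so the chain can escape).
#'
#' @param length tunnel length in Angstrom (PTC plane to mouth).
#' @param radius base inner (lumen) radius in Angstrom.
#' @param waists optional data frame with columns `z`, `r` and optionally
#'   `width` (Gaussian sigma, default 4 A): local constrictions.
#' @param spacing wall lattice spacing in Angstrom (<= 2 so a 3-A probe
#'   cannot leak through).
#' @param shells number of concentric atom shells (default 2).
#' @param jitter uniform lattice jitter amplitude in Angstrom.
#' @param cap_bottom,cap_top close the tunnel ends with atom discs.
#' @param end_margin wall extension beyond both ends in Angstrom.
#' @param vdw pseudo-atom van der Waals radius.
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @param check run the impermeability self-check (probe radius 3 A;
#'   applies when both caps are present).
#' @return a `ribosome_cutout`.
#' @export
make_toy_tunnel <- function(length = 80, radius = 10, waists = NULL,
                            spacing = 2, shells = 2, jitter = 0.3,
                            cap_bottom = TRUE, cap_top = TRUE,
                            end_margin = 6, vdw = 1.7, seed = 1,
                            check = TRUE) {
  if (spacing > 2) abort("`spacing` must be <= 2 A for an impermeable wall")
  if (radius <= 0 || length <= 0) abort("positive length and radius required")
  r_of_z <- function(z) {
    r <- rep(radius, base::length(z))
    if (!is.null(waists)) {
      for (k in seq_len(nrow(waists))) {
        w <- if ("width" %in% names(waists)) waists$width[k] else 4
        r <- r - (radius - waists$r[k]) * exp(-(z - waists$z[k])^2 / (2 * w^2))
      }
    }
    if (any(r <= 0)) abort("inner radius profile must stay positive")
    r
  }
  set.seed(seed)
  zlo <- -end_margin
  zhi <- length + end_margin
  zs <- seq(zlo, zhi, by = spacing * 0.9)
  pts <- list()
  for (z in zs) {
    rin <- r_of_z(min(max(z, 0), length))
    for (s in seq_len(shells)) {
      rs <- rin + vdw + (s - 1) * spacing * 0.9
      m <- max(6L, ceiling(2 * pi * rs / spacing))
      th <- (seq_len(m) - 1) * 2 * pi / m + runif(1, 0, 2 * pi / m)
      pts[[base::length(pts) + 1L]] <-
        cbind(rs * cos(th), rs * sin(th), z) +
        matrix(runif(3 * m, -jitter, jitter), ncol = 3)
    }
  }
  cap <- function(zc) {
    rmax <- r_of_z(min(max(zc, 0), length)) + vdw + shells * spacing
    rr <- seq(0, rmax, by = spacing * 0.9)
    do.call(rbind, lapply(rr, function(r0) {
      m <- max(1L, ceiling(2 * pi * max(r0, spacing / 4) / spacing))
      th <- (seq_len(m) - 1) * 2 * pi / m + runif(1, 0, 2 * pi / m)
      cbind(r0 * cos(th), r0 * sin(th), zc) +
        matrix(runif(3 * m, -jitter, jitter), ncol = 3)
    }))
  }
  if (cap_bottom) pts[[base::length(pts) + 1L]] <- cap(zlo)
  if (cap_top) pts[[base::length(pts) + 1L]] <- cap(zhi)
  xyz <- do.call(rbind, pts)
  at <- atomset(xyz, element = "C", resname = "WAL", chain = "W",
                kind = "other")
  cut <- structure(list(atoms = at, n_kept = nrow(at), n_total = nrow(at),
                        frame = tunnel_frame(c(0, 0, 0), c(0, 0, 1),
                                             radius + 20)),
                   class = "ribosome_cutout")
  if (check && cap_bottom && cap_top) .check_impermeable(cut)
  cut
}

# the lumen flood fill (probe 3 A, no ray marking) must not reach the grid
# boundary: otherwise the wall leaks
.check_impermeable <- function(cutout, probe = 3) {
  g <- rasterize(cutout, spacing = 1, probe_radius = probe)
  none_outside <- rep(FALSE, prod(g$dims))
  seed_idx <- .seed_index(g, c(0, 0, 0.5))
  fin <- cpp_flood_fill(g$labels, none_outside, g$dims, seed_idx - 1L)
  cav <- which(fin == 3L)
  nx <- g$dims[1]; ny <- g$dims[2]; nz <- g$dims[3]
  ix <- (cav - 1L) %% nx
  iy <- ((cav - 1L) %/% nx) %% ny
  iz <- (cav - 1L) %/% (nx * ny)
  if (any(ix == 0 | iy == 0 | iz == 0 | ix == nx - 1 | iy == ny - 1 |
          iz == nz - 1))
    abort("synthetic tunnel wall leaks: probe escaped the lumen")
  invisible(TRUE)
}

#' Toy native models with ideal geometry
#'
#' Calpha traces with ideal secondary-structure geometry; contacts are
#' assigned by a Calpha-distance cutoff (7.5 A at sequence separation >= 3),
#' standing in for the all-atom overlap criterion that synthetic traces
#' without side chains cannot use.
#'
#' @param kind `"helix"` (1.5 A rise, 100 degrees per residue),
#'   `"hairpin"` (two antiparallel strands 4.8 A apart) or `"two_helix"`
#'   (a helical hairpin).
#' @param n number of residues (>= 8).
#' @param seed RNG seed (a tiny symmetric-breaking jitter is seeded).
#' @param cutoff,min_sep contact rule parameters.
#' @return a `native_model`.
#' @export
make_toy_native <- function(kind = c("helix", "hairpin", "two_helix"),
                            n = 16, seed = 1, cutoff = 7.5, min_sep = 3) {
  kind <- match.arg(kind)
  if (n < 8) abort("need at least 8 residues")
  set.seed(seed)
  helix <- function(m, phase = 0, origin = c(0, 0, 0), flip = FALSE) {
    k <- seq_len(m) - 1
    th <- phase + k * 100 * pi / 180
    z <- k * 1.5
    if (flip) z <- rev(z)
    cbind(2.3 * cos(th), 2.3 * sin(th), z) +
      matrix(origin, m, 3, byrow = TRUE)
  }
  xyz <- switch(kind,
    helix = helix(n),
    hairpin = {
      m <- n %/% 2
      s1 <- cbind(0, 0.6 * (-1)^(seq_len(m)), 3.4 * (seq_len(m) - 1))
      extra <- n - 2 * m
      turn <- if (extra > 0)
        cbind(2.4, 0, 3.4 * (m - 1) + 2.2) else NULL
      s2 <- cbind(4.8, 0.6 * (-1)^(seq_len(m)), 3.4 * rev(seq_len(m) - 1))
      rbind(s1, turn, s2)
    },
    two_helix = {
      m <- (n - 3) %/% 2
      h1 <- helix(m)
      top <- 1.5 * (m - 1)
      loop <- cbind(c(2.5, 5.0, 7.5), 1.0, top + c(2.0, 2.8, 2.0))
      h2 <- helix(n - m - 3, phase = pi, origin = c(10, 0, 0), flip = TRUE)
      h2[, 3] <- h2[, 3] - (max(h2[, 3]) - top)
      rbind(h1, loop, h2)
    })
  xyz <- xyz + matrix(rnorm(3 * nrow(xyz), sd = 0.01), ncol = 3)
  # rescale consecutive distances to ~3.8 A bond lengths
  d <- sqrt(rowSums(diff(xyz)^2))
  native_model_from_ca(xyz * (3.8 / mean(d)), cutoff = cutoff,
                       min_sep = min_sep)
}

#' Parametric knotted and unknotted open curves
#'
#' Samples a (2,3) torus trefoil or a figure-eight curve at `n` points,
#' opens it at a gap, and appends straight tails; the unknot is a helical
#' arc. Useful as ground truth for the knot pipeline.
#'
#' @param kind `"trefoil"`, `"figure_eight"` or `"unknot"`.
#' @param n number of curve points (>= 60).
#' @param tail number of straight tail points appended at each end.
#' @param scale overall scale factor in Angstrom.
#' @return an n x 3 matrix (open polyline).
#' @export
make_knot_curve <- function(kind = c("trefoil", "figure_eight", "unknot"),
                            n = 120, tail = 0, scale = 5) {
  kind <- match.arg(kind)
  if (n < 60) abort("need at least 60 curve points")
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  xyz <- switch(kind,
    trefoil = cbind(sin(t) + 2 * sin(2 * t),
                    cos(t) - 2 * cos(2 * t),
                    -sin(3 * t)),
    figure_eight = cbind((2 + cos(2 * t)) * cos(3 * t),
                         (2 + cos(2 * t)) * sin(3 * t),
                         sin(4 * t)),
    unknot = cbind(cos(t / 2), sin(t / 2), t / (2 * pi)))
  xyz <- xyz * scale
  if (kind != "unknot") {
    # open the loop at its most distal point so the cut ends sit on the
    # outside of the knot (clean radial closure, stable KMT core)
    rel <- sweep(xyz, 2, colMeans(xyz))
    i0 <- which.max(rowSums(rel^2))
    idx <- ((i0 + seq_len(n) - 1L) - 1L) %% n + 1L
    xyz <- xyz[idx[seq_len(n - max(3L, round(0.04 * n)))], , drop = FALSE]
    n <- nrow(xyz)
  }
  if (tail > 0) {
    d1 <- .unit(xyz[1, ] - xyz[2, ])
    d2 <- .unit(xyz[n, ] - xyz[n - 1, ])
    step <- scale / 2
    t1 <- xyz[rep(1, tail), ] + outer(rev(seq_len(tail)) * step, d1)
    t2 <- xyz[rep(n, tail), ] + outer(seq_len(tail) * step, d2)
    xyz <- rbind(t1, xyz, t2)
  }
  unname(xyz)
}
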