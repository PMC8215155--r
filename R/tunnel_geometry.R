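# Grid-probe tunnel geometry: rasterization, rotation-averaged probe
# accessibility, cavity volume, surface-to-volume, axial profile and
# constriction sites.

.grid_from_atoms <- function(xyz, radii, spacing, probe) {
  pad <- 2 * probe
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / spacing))
  list(origin = lo, dims = dims, spacing = spacing)
}

#' Rasterize a cut-out onto a probe-inflated occupancy grid
#'
#' A cell is labelled ATOM iff its centre lies within (vdW radius +
#' `probe_radius`) of any wall atom, so probe accessibility reduces to plain
#' cell reachability afterwards.
#'
#' @param cutout a `ribosome_cutout` (tunnel-frame coordinates).
#' @param spacing grid spacing in Angstrom (default 1); must not exceed the
#'   probe radius.
#' @param probe_radius probing-particle radius in Angstrom (default 4).
#' @return an object of class `tunnel_grid`.
#' @export
rasterize <- function(cutout, spacing = 1, probe_radius = 4) {
  stopifnot(inherits(cutout, "ribosome_cutout"))
  if (spacing > probe_radius)
    abort("`spacing` must not exceed `probe_radius`")
  at <- cutout$atoms
  if (!nrow(at)) abort("empty cut-out")
  xyz <- cbind(at$x, at$y, at$z)
  radii <- vdw_radii(at$element)
  g <- .grid_from_atoms(xyz, radii, spacing, probe_radius)
  lab <- cpp_rasterize(xyz, radii, g$origin, g$dims, spacing, probe_radius)
  structure(list(labels = lab, dims = g$dims, origin = g$origin,
                 spacing = spacing, probe = probe_radius,
                 xyz = xyz, radii = radii),
            class = "tunnel_grid")
}

#' @export
print.tunnel_grid <- function(x, ...) {
  cat(sprintf("<tunnel_grid> %d x %d x %d cells at %g A (probe %g A), %d ATOM\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, x$probe,
              sum(x$labels == 1L)))
  invisible(x)
}

.cell_of <- function(grid, p) {
  as.integer(floor((p - grid$origin) / grid$spacing))
}

.cell_index <- function(dims, cx) {
  # 0-based cell coords -> 1-based flat index; NA when out of bounds
  ok <- cx[, 1] >= 0 & cx[, 2] >= 0 & cx[, 3] >= 0 &
    cx[, 1] < dims[1] & cx[, 2] < dims[2] & cx[, 3] < dims[3]
  idx <- cx[, 1] + dims[1] * (cx[, 2] + dims[2] * cx[, 3]) + 1L
  idx[!ok] <- NA_integer_
  idx
}

# nearest unoccupied cell to the seed point (searched within a small box);
# an occupied neighbourhood means the frame is misplaced
.seed_index <- function(grid, seed_point, search = 8) {
  dims <- grid$dims; sp <- grid$spacing
  c0 <- .cell_of(grid, seed_point)
  w <- ceiling(search / sp)
  rng <- lapply(1:3, function(d)
    max(0, c0[d] - w):min(dims[d] - 1, c0[d] + w))
  cx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  idx <- .cell_index(dims, cx)
  ok <- !is.na(idx) & grid$labels[idx] != 1L
  if (!any(ok))
    abort("all cells near the PTC seed are occupied; the tunnel frame looks misplaced")
  ctr <- sweep((cx[ok, , drop = FALSE] + 0.5) * sp, 2, -grid$origin)
  d2 <- rowSums(sweep(ctr, 2, seed_point)^2)
  idx[ok][which.min(d2)]
}

.single_rotation_cavity <- function(xyz, radii, spacing, probe, rot,
                                    seed_point) {
  rx <- xyz %*% t(rot)
  g <- .grid_from_atoms(rx, radii, spacing, probe)
  lab <- cpp_rasterize(rx, radii, g$origin, g$dims, spacing, probe)
  out <- cpp_ray_sweep(lab, g$dims)
  sp <- as.numeric(rot %*% seed_point)
  idx <- .seed_index(list(labels = lab, dims = g$dims, origin = g$origin,
                          spacing = spacing), sp)
  fin <- cpp_flood_fill(lab, out, g$dims, idx - 1L)
  list(labels = fin, dims = g$dims, origin = g$origin,
       volume = sum(fin == 3L) * spacing^3)
}

#' Rotation-averaged probe accessibility and cavity identification
#'
#' For each rotation of the cut-out, probe rays enter along all six grid
#' directions from outside; swept empty cells are OUTSIDE for that rotation
#' and the tunnel cavity is the 6-connected component containing the PTC
#' seed. Across rotations, a reference-grid cell is finally OUTSIDE when a
#' majority of rotations marked it so; the remaining empty cells seed the
#' final flood fill. Per-rotation cavity volumes are recorded and their
#' spread is the reported uncertainty.
#'
#' @param grid a `tunnel_grid` from [rasterize()].
#' @param rotations either a count (identity + n-1 seeded uniform random
#'   rotations; default 10) or a list of 3x3 rotation matrices starting with
#'   the identity.
#' @param seed RNG seed for the random rotations.
#' @param seed_point cavity seed in tunnel-frame coordinates (default the
#'   PTC origin).
#' @param combine `"majority"` (default), `"union"` (OUTSIDE if any rotation
#'   marked it) or `"intersection"` (all rotations).
#' @return an object of class `cavity_map`.
#' @export
probe_accessibility <- function(grid, rotations = 10, seed = 1,
                                seed_point = c(0, 0, 0),
                                combine = c("majority", "union",
                                            "intersection")) {
  stopifnot(inherits(grid, "tunnel_grid"))
  combine <- match.arg(combine)
  if (is.numeric(rotations) && length(rotations) == 1) {
    nrot <- as.integer(rotations)
    if (nrot < 1) abort("need at least one rotation")
    rots <- c(list(diag(3)), {
      set.seed(seed)
      lapply(seq_len(nrot - 1), function(i) .random_rotation())
    })
  } else {
    rots <- rotations
    if (!length(rots)) abort("need at least one rotation")
  }
  seed_idx <- .seed_index(grid, seed_point)

  vols <- numeric(length(rots))
  votes <- integer(length(grid$labels))
  empty <- which(grid$labels == 0L)
  centers <- cbind(
    (empty - 1L) %% grid$dims[1],
    ((empty - 1L) %/% grid$dims[1]) %% grid$dims[2],
    (empty - 1L) %/% (grid$dims[1] * grid$dims[2]))
  centers <- sweep((centers + 0.5) * grid$spacing, 2, -grid$origin)

  for (r in seq_along(rots)) {
    res <- .single_rotation_cavity(grid$xyz, grid$radii, grid$spacing,
                                   grid$probe, rots[[r]], seed_point)
    vols[r] <- res$volume
    rc <- centers %*% t(rots[[r]])
    cx <- matrix(as.integer(floor(sweep(rc, 2, res$origin) / grid$spacing)),
                 ncol = 3)
    idx <- .cell_index(res$dims, cx)
    lab_r <- ifelse(is.na(idx), 2L, res$labels[idx])
    votes[empty] <- votes[empty] + as.integer(lab_r == 2L)
  }

  nrot <- length(rots)
  outside <- switch(combine,
    majority = votes > nrot / 2,
    union = votes > 0L,
    intersection = votes == nrot)
  fin <- cpp_flood_fill(grid$labels, outside, grid$dims, seed_idx - 1L)
  structure(list(labels = fin, dims = grid$dims, origin = grid$origin,
                 spacing = grid$spacing, probe = grid$probe,
                 n_rotations = nrot, volumes = vols, combine = combine),
            class = "cavity_map")
}

#' @export
print.cavity_map <- function(x, ...) {
  v <- tunnel_volume(x)
  cat(sprintf("<cavity_map> probe %g A, %d rotations: V = %.0f +/- %.0f A^3, %d cavity cells\n",
              x$probe, x$n_rotations, v$volume, v$spread,
              sum(x$labels == 3L)))
  invisible(x)
}

#' Exit-tunnel volume with its rotation spread
#'
#' @param cavity a `cavity_map`.
#' @return a one-row tibble with `volume` (mean over rotations, A^3),
#'   `spread` (standard deviation over rotations), `probe_radius` and
#'   `n_rotations`.
#' @export
tunnel_volume <- function(cavity) {
  stopifnot(inherits(cavity, "cavity_map"))
  tibble(volume = mean(cavity$volumes),
         spread = if (length(cavity$volumes) > 1) sd(cavity$volumes) else 0,
         probe_radius = cavity$probe,
         n_rotations = cavity$n_rotations)
}

#' Surface-area-to-volume ratio of the cavity
#'
#' The surface is counted as cavity cell faces adjacent to an atom cell or
#' to an outside cell that itself touches an atom cell, times spacing^2.
#'
#' @param cavity a `cavity_map`.
#' @return the ratio in 1/Angstrom.
#' @export
surface_to_volume <- function(cavity) {
  stopifnot(inherits(cavity, "cavity_map"))
  ncav <- sum(cavity$labels == 3L)
  if (ncav == 0) abort("cavity is empty")
  faces <- cpp_surface_faces(cavity$labels, cavity$dims)
  (faces * cavity$spacing^2) / (ncav * cavity$spacing^3)
}

#' Axial cross-section profile of the cavity
#'
#' @param cavity a `cavity_map`.
#' @param bin_width axial bin width in Angstrom (default 2).
#' @return a tibble of class `tunnel_profile` with columns `z` (bin centre,
#'   A from the PTC), `area` (A^2) and `r_eff` = sqrt(area/pi).
#' @export
axial_profile <- function(cavity, bin_width = 2) {
  stopifnot(inherits(cavity, "cavity_map"))
  cav <- which(cavity$labels == 3L)
  if (!length(cav)) abort("cavity is empty")
  nxy <- cavity$dims[1] * cavity$dims[2]
  zc <- cavity$origin[3] + ((cav - 1L) %/% nxy + 0.5) * cavity$spacing
  edges <- seq(floor(min(zc) / bin_width) * bin_width,
               ceiling(max(zc) / bin_width) * bin_width, by = bin_width)
  if (length(edges) < 2) edges <- c(edges, edges + bin_width)
  counts <- table(cut(zc, edges, include.lowest = TRUE))
  area <- as.numeric(counts) * cavity$spacing^3 / bin_width
  out <- tibble(z = head(edges, -1) + bin_width / 2,
                area = area, r_eff = sqrt(area / pi))
  structure(out, class = c("tunnel_profile", class(out)),
            bin_width = bin_width, spacing = cavity$spacing)
}

#' Locate constriction sites along the tunnel axis
#'
#' Local minima of the (moving-average smoothed) effective radius, ranked
#' by increasing distance from the PTC: CS1 is the first, CS2 the second.
#' Minima closer than `merge_dist` are merged into the deeper one.
#'
#' @param profile a `tunnel_profile`.
#' @param smooth_bins moving-average window in bins (default 3).
#' @param merge_dist merge radius in Angstrom (default 5).
#' @param min_depth minimal prominence in Angstrom (default 1): a minimum
#'   counts only when the smoothed radius rises at least this much above it
#'   on both sides, which suppresses grid-noise wiggles.
#' @param z_range optional c(min, max) window of axial positions to search
#'   (e.g. to exclude closed tunnel ends).
#' @return a tibble with columns `rank` ("CS1", "CS2", ...), `z` and
#'   `r_eff`; zero rows when the profile has no interior minimum.
#' @export
find_constrictions <- function(profile, smooth_bins = 3, merge_dist = 5,
                               min_depth = 1, z_range = NULL) {
  stopifnot(inherits(profile, "tunnel_profile"))
  p <- profile
  if (!is.null(z_range))
    p <- p[p$z >= z_range[1] & p$z <= z_range[2], , drop = FALSE]
  p <- p[p$area > 0, , drop = FALSE]
  if (nrow(p) < 5) abort("profile needs at least 5 non-empty bins")
  k <- max(1L, as.integer(smooth_bins))
  r <- as.numeric(stats::filter(p$r_eff, rep(1 / k, k), sides = 2))
  r[is.na(r)] <- p$r_eff[is.na(r)]
  n <- length(r)
  is_min <- c(FALSE, r[2:(n - 1)] < r[1:(n - 2)] & r[2:(n - 1)] < r[3:n],
              FALSE)
  cand <- which(is_min)
  # prominence filter: the smoothed radius must rise by min_depth on both
  # sides before the profile ends or drops below the minimum again
  if (length(cand) && min_depth > 0) {
    keep <- vapply(cand, function(i) {
      lmax <- -Inf
      for (k in seq(i - 1, 1)) {
        if (r[k] < r[i]) break
        lmax <- max(lmax, r[k])
      }
      rmax <- -Inf
      for (k in seq(i + 1, n)) {
        if (r[k] < r[i]) break
        rmax <- max(rmax, r[k])
      }
      min(lmax, rmax) - r[i] >= min_depth
    }, logical(1))
    cand <- cand[keep]
  }
  if (!length(cand)) {
    return(tibble(rank = character(), z = numeric(), r_eff = numeric()))
  }
  # merge minima closer than merge_dist, keeping the deeper
  cand <- cand[order(p$z[cand])]
  kept <- integer()
  for (i in cand) {
    if (length(kept) && abs(p$z[i] - p$z[tail(kept, 1)]) < merge_dist) {
      if (r[i] < r[tail(kept, 1)]) kept[length(kept)] <- i
    } else kept <- c(kept, i)
  }
  tibble(rank = paste0("CS", seq_along(kept)),
         z = p$z[kept], r_eff = r[kept])
}

#' @rdname tidy-ribotunnel
#' @export
tidy.cavity_map <- function(x, ...) {
  tibble(rotation = seq_along(x$volumes), volume = x$volumes)
}

#' @rdname glance-ribotunnel
#' @export
glance.cavity_map <- function(x, ...) {
  v <- tunnel_volume(x)
  tibble(volume = v$volume, spread = v$spread,
         surface_to_volume = surface_to_volume(x),
         probe_radius = x$probe, n_rotations = x$n_rotations,
         n_cavity_cells = sum(x$labels == 3L))
}

#' Write the cavity label grid in OpenDX scalar format
#'
#' Cell values: 0 empty, 1 atom, 2 outside, 3 cavity; loadable as a density
#' map in the usual structure viewers.
#'
#' @param cavity a `cavity_map`.
#' @param path output path (conventionally `.dx`).
#' @return invisibly, `path`.
#' @export
write_cavity_grid <- function(cavity, path) {
  d <- cavity$dims
  con <- file(path, "w")
  on.exit(close(con))
  org <- cavity$origin + cavity$spacing / 2
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.3f %.3f %.3f", org[1], org[2], org[3]),
    sprintf("delta %.3f 0 0", cavity$spacing),
    sprintf("delta 0 %.3f 0", cavity$spacing),
    sprintf("delta 0 0 %.3f", cavity$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX expects z fastest; our flat index runs x fastest
  arr <- array(cavity$labels, dim = d)
  vals <- as.numeric(aperm(arr, c(3, 2, 1)))
  full <- length(vals) - length(vals) %% 3
  if (full > 0) {
    m <- matrix(vals[seq_len(full)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%g %g %g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (full < length(vals))
    writeLines(paste(vals[(full + 1):length(vals)], collapse = " "), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Write cavity cells as pseudo-atoms for visual overlays
#'
#' @param cavity a `cavity_map`.
#' @param path output PDB path.
#' @return invisibly, `path`.
#' @export
write_cavity_pdb <- function(cavity, path) {
  cav <- which(cavity$labels == 3L)
  nx <- cavity$dims[1]; nxy <- nx * cavity$dims[2]
  xyz <- cbind((cav - 1L) %% nx, ((cav - 1L) %/% nx) %% cavity$dims[2],
               (cav - 1L) %/% nxy)
  xyz <- sweep((xyz + 0.5) * cavity$spacing, 2, -cavity$origin)
  write_cutout_pdb(atomset(xyz, element = "O", resname = "CAV"), path)
}
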