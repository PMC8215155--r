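# Open-chain knot detection: KMT reduction, radial-sphere closure,
# Alexander determinant from the crossing diagram, and knot-core trimming.

#' KMT reduction of a polygonal chain
#'
#' Iteratively removes vertex i whenever the triangle (i-1, i, i+1) is
#' pierced by no other chain segment; endpoints of an open chain are never
#' removed. The reduction preserves the chain topology.
#'
#' @param points n x 3 matrix of vertices.
#' @param closed treat the chain as a closed loop.
#' @return the reduced matrix of vertices.
#' @export
kmt_reduce <- function(points, closed = FALSE) {
  .assert_matrix3(points)
  if (nrow(points) < 3) return(points)
  cpp_kmt(points, isTRUE(closed))
}

# close an open chain: extend both termini radially from the centroid to a
# sphere of radius 3x the maximal extent, then join along a great circle
.close_chain <- function(points, seed = 1, arc_points = 24) {
  ctr <- colMeans(points)
  rel <- sweep(points, 2, ctr)
  R <- 3 * max(sqrt(rowSums(rel^2)), 1)
  for (attempt in 0:10) {
    e1 <- rel[1, ]; e2 <- rel[nrow(points), ]
    if (attempt > 0) {
      set.seed(seed + attempt)
      e1 <- e1 + rnorm(3, sd = 0.02 * R)
      e2 <- e2 + rnorm(3, sd = 0.02 * R)
    }
    if (sqrt(sum(e1^2)) < 1e-9 || sqrt(sum(e2^2)) < 1e-9) next
    u1 <- .unit(e2)  # C-terminus direction
    u2 <- .unit(e1)  # N-terminus direction
    ang <- acos(max(-1, min(1, sum(u1 * u2))))
    if (abs(pi - ang) < 1e-6) next  # antipodal: no unique great circle
    arc <- if (ang < 1e-8) {
      matrix(numeric(), 0, 3)
    } else {
      axis <- .unit(pracma_cross(u1, u2))
      perp <- .unit(pracma_cross(axis, u1))
      ts <- seq(0, ang, length.out = arc_points + 2)
      ts <- ts[-c(1, length(ts))]
      t(vapply(ts, function(a) R * (cos(a) * u1 + sin(a) * perp),
               numeric(3)))
    }
    closed <- rbind(points,
                    sweep(rbind(R * u1, arc, R * u2), 2, ctr, FUN = "+"))
    return(closed)
  }
  abort("could not close the chain (degenerate termini geometry)")
}

# |Alexander polynomial at t = -1| from a crossing list of a closed chain
# projected on the xy plane. At t = -1 each crossing contributes +2 on its
# over-arc and -1 on each of the two under-arcs regardless of sign.
.alexander_det <- function(cr) {
  m <- length(cr$si)
  if (m == 0) return(1)
  pos_i <- cr$si + cr$ti          # position along the closed chain
  pos_j <- cr$sj + cr$tj
  over_pos <- ifelse(cr$over_first == 1, pos_i, pos_j)
  under_pos <- ifelse(cr$over_first == 1, pos_j, pos_i)
  u <- sort(under_pos)
  arc_of <- function(p) {
    # arc k spans (u[k], u[k+1]); positions before u[1] or after u[m]
    # belong to the wrap-around arc m
    k <- findInterval(p, u)
    k[k == 0] <- m
    k
  }
  A <- matrix(0L, m, m)
  ord <- order(under_pos)
  for (r in seq_len(m)) {
    cidx <- ord[r]                 # crossing whose under position is u[r]
    inc <- if (r == 1) m else r - 1
    out <- r
    ov <- arc_of(over_pos[cidx])
    A[r, ov] <- A[r, ov] + 2L
    A[r, inc] <- A[r, inc] - 1L
    A[r, out] <- A[r, out] - 1L
  }
  if (m == 1) return(1)
  abs(round(det(A[-m, -m, drop = FALSE])))
}

#' Knot type of a chain via the Alexander determinant
#'
#' Open chains are closed by extending both termini radially from the
#' centroid to a sphere of three times the maximal extent and joining them
#' along a great circle, KMT-reduced, projected under a seeded random
#' rotation (retried while the diagram is degenerate), and typed by
#' |Alexander polynomial at -1|: 1 = unknot, 3 = trefoil, otherwise
#' other(determinant).
#'
#' @param points n x 3 vertex matrix (>= 3 vertices).
#' @param closed is the chain already a closed loop?
#' @param seed seed for the projection rotations and closure jitter.
#' @return an object of class `knot_report` with `type`, `determinant`,
#'   `closure`, and NULL `core`.
#' @export
knot_type <- function(points, closed = FALSE, seed = 1) {
  .assert_matrix3(points)
  if (nrow(points) < 3) abort("need at least 3 points")
  loop <- if (closed) points else .close_chain(points, seed = seed)
  red <- cpp_kmt(loop, TRUE)
  det <- NA_real_
  set.seed(seed)
  for (attempt in 1:50) {
    rot <- if (attempt == 1) diag(3) else .random_rotation()
    cr <- cpp_crossings(red %*% t(rot))
    if (!cr$degenerate) {
      det <- .alexander_det(cr)
      break
    }
  }
  if (is.na(det)) abort("projection stayed degenerate after 50 rotations")
  type <- if (det == 1) "unknot" else if (det == 3) "trefoil"
  else sprintf("other(%d)", as.integer(det))
  structure(list(type = type, determinant = det, core = NULL,
                 closure = if (closed) "closed" else "radial"),
            class = "knot_report")
}

#' @export
print.knot_report <- function(x, ...) {
  cat(sprintf("<knot_report> %s (|Alexander(-1)| = %g, closure: %s)\n",
              x$type, x$determinant, x$closure))
  if (!is.null(x$core))
    cat(sprintf("  knot core: residues %d-%d\n", x$core[1], x$core[2]))
  invisible(x)
}

#' Knot core by bidirectional end-trimming
#'
#' Shortens the chain from each terminus while the remaining sub-chain
#' stays knotted; the reported core is the minimal knotted sub-chain, as
#' residue indices of the input chain.
#'
#' @param points n x 3 vertex matrix of an open chain.
#' @param seed projection/closure seed.
#' @param step trimming stride in vertices (refined to single vertices at
#'   the boundary).
#' @return a `knot_report` whose `core` is c(first, last), or type
#'   "unknot" with NULL core when the chain is not knotted.
#' @export
knot_core <- function(points, seed = 1, step = 1) {
  full <- knot_type(points, seed = seed)
  if (full$type == "unknot") return(full)
  n <- nrow(points)
  knotted <- function(a, b) {
    if (b - a + 1 < 3) return(FALSE)
    knot_type(points[a:b, , drop = FALSE], seed = seed)$determinant != 1
  }
  a <- 1L
  while (a < n - 2 && knotted(a + 1L, n)) a <- a + 1L
  b <- n
  while (b > a + 2 && knotted(a, b - 1L)) b <- b - 1L
  out <- full
  out$core <- c(a, b)
  out
}
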