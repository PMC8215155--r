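# shared test helpers: numerical gradients, small structures, random walks

# central-difference gradient of a scalar energy function of an n x 3 matrix
num_grad <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_len(nrow(x))) {
    for (d in 1:3) {
      xp <- x; xm <- x
      xp[i, d] <- xp[i, d] + h
      xm[i, d] <- xm[i, d] - h
      g[i, d] <- (f(xp) - f(xm)) / (2 * h)
    }
  }
  g
}

# an atomset of two alanine-like residues (5-residue chain, the middle three
# far away) whose CB atoms sit `d` apart; exercises the overlap criterion
dipeptide_atomset <- function(d) {
  res <- function(resno, origin, with_cb = TRUE) {
    atoms <- c("N", "CA", "C", if (with_cb) "CB")
    elem <- c("N", "C", "C", if (with_cb) "C")
    off <- rbind(c(0, 0, 0), c(0, 0, 1.5), c(0, 0, 3), c(0, 1.6, 1.5))
    off <- off[seq_along(atoms), , drop = FALSE]
    tibble::tibble(
      x = origin[1] + off[, 1], y = origin[2] + off[, 2],
      z = origin[3] + off[, 3],
      element = elem, atom = atoms, resname = "ALA", resno = resno,
      chain = "A", het = FALSE, kind = "protein")
  }
  # CB of residue 1 at (0, 1.6, 1.5); CB of residue 5 at (d, 1.6, 1.5)
  # backbone of residue 5 shifted so only the CB pair can overlap
  r5 <- res(5L, c(d, 0, 0))
  tab <- dplyr::bind_rows(
    res(1L, c(0, 0, 0)),
    res(2L, c(200, 0, 0), with_cb = FALSE),
    res(3L, c(300, 0, 0), with_cb = FALSE),
    res(4L, c(400, 0, 0), with_cb = FALSE),
    r5)
  structure(tab, class = c("atomset", class(tab)))
}

# seeded self-avoiding random walk of n steps (bond length b, exclusion rb)
sa_walk <- function(n, seed, b = 3.8, rb = 3.0) {
  set.seed(seed)
  x <- matrix(0, n + 1, 3)
  i <- 2L
  tries <- 0L
  while (i <= n + 1) {
    step <- rnorm(3)
    cand <- x[i - 1, ] + b * step / sqrt(sum(step^2))
    d2 <- rowSums(sweep(x[seq_len(i - 1), , drop = FALSE], 2, cand)^2)
    if (all(d2 > rb^2)) {
      x[i, ] <- cand
      i <- i + 1L
    } else {
      tries <- tries + 1L
      if (tries > 200L) { # restart rather than loop forever
        i <- 2L; tries <- 0L
      }
    }
  }
  x
}

# closed parametric trefoil ((2,3) torus curve)
closed_trefoil <- function(n = 120, scale = 5) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(sin(t) + 2 * sin(2 * t), cos(t) - 2 * cos(2 * t), -sin(3 * t)) * scale
}
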