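# shared helpers: van der Waals radii, frames, rotations, small validators

# element-keyed vdW radii (Angstrom); anything else falls back to 1.7
.vdw_table <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, H = 1.20)

#' Van der Waals radii for a vector of element symbols
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param table named numeric vector of radii in Angstrom; elements absent
#'   from the table get `default`.
#' @param default fallback radius in Angstrom.
#' @return numeric vector of radii.
#' @export
vdw_radii <- function(element, table = NULL, default = 1.70) {
  tab <- table %||% .vdw_table
  r <- unname(tab[toupper(element)])
  r[is.na(r)] <- default
  r
}

.aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V", MSE = "M")

.nuc_res <- c("A", "U", "G", "C", "I", "DA", "DG", "DC", "DT", "DU", "DI")

.residue_kind <- function(resname) {
  ifelse(resname %in% names(.aa3), "protein",
         ifelse(resname %in% .nuc_res, "RNA", "other"))
}

# formal charges of the standard residues; histidine treated as neutral
.residue_charge <- function(resname) {
  ch <- rep(0L, length(resname))
  ch[resname %in% c("ASP", "GLU")] <- -1L
  ch[resname %in% c("LYS", "ARG")] <- 1L
  ch
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort("zero-length vector cannot be normalised")
  v / n
}

# right-handed orthonormal basis (u, v, axis) with axis as +z
.frame_basis <- function(axis) {
  a <- .unit(axis)
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(pracma_cross(ref, a))
  v <- pracma_cross(a, u)
  rbind(u, v, a)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# uniform random rotation matrix (Arvo's method via quaternions)
.random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

.assert_matrix3 <- function(x, name = "points") {
  if (!is.matrix(x) || ncol(x) != 3 || !is.numeric(x))
    abort(sprintf("`%s` must be a numeric matrix with 3 columns", name))
  if (any(!is.finite(x))) abort(sprintf("`%s` contains non-finite values", name))
  invisible(x)
}
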