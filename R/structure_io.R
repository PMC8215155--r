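# Structure parsing, the PTC-anchored tunnel frame, the cylindrical
# cut-out, and Calpha native models with overlap-criterion contact maps.

#' Load a structure file into an atom table
#'
#' Reads a PDB or mmCIF file (via bio3d) and returns every atom record as a
#' tibble of class `atomset`: positions in Angstrom, element, atom and
#' residue names, residue number, chain, a `kind` column
#' (protein/RNA/other) and a heteroatom flag. Alternate locations beyond the
#' first are dropped.
#'
#' @param path file path.
#' @param format `"auto"` (from the extension), `"pdb"` or `"cif"`.
#' @return a tibble of class `atomset` with attributes `n_atoms` and `source`.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path) else
      bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE),
    error = function(e)
      abort(paste0("could not parse ", path, " as ", format, ": ",
                   conditionMessage(e))))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0)
    abort(paste0("no atom records in ", path))
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == "")) {
    elem <- gsub("[^A-Za-z].*$", "", trimws(at$elety))
    elem <- substr(elem, 1, 1)
  }
  elem[is.na(elem) | elem == ""] <-
    substr(gsub("[0-9 ]", "", at$elety[is.na(elem) | elem == ""]), 1, 1)
  out <- tibble(
    x = at$x, y = at$y, z = at$z,
    element = toupper(trimws(elem)),
    atom = trimws(at$elety),
    resname = trimws(at$resid),
    resno = at$resno,
    chain = as.character(at$chain),
    het = at$type != "ATOM",
    kind = .residue_kind(trimws(at$resid)))
  if (any(!is.finite(out$x + out$y + out$z)))
    abort("non-finite coordinates in structure")
  structure(out, class = c("atomset", class(out)),
            n_atoms = nrow(out), source = path)
}

#' Build an atomset from bare coordinates (mostly for synthetic walls)
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param element,resname,chain,kind recycled metadata columns.
#' @param resno residue numbers (default 1..n).
#' @return an `atomset` tibble.
#' @export
atomset <- function(xyz, element = "C", resname = "UNK", chain = "X",
                    resno = NULL, kind = NULL) {
  .assert_matrix3(xyz, "xyz")
  n <- nrow(xyz)
  out <- tibble(
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = rep_len(toupper(element), n),
    atom = rep_len("PS", n),
    resname = rep_len(resname, n),
    resno = resno %||% seq_len(n),
    chain = rep_len(chain, n),
    het = FALSE,
    kind = rep_len(kind %||% .residue_kind(rep_len(resname, n)), n))
  structure(out, class = c("atomset", class(out)), n_atoms = n,
            source = "constructed")
}

#' Define the PTC-anchored tunnel coordinate frame
#'
#' @param origin PTC position in file coordinates (length-3, Angstrom).
#' @param axis direction from the PTC toward the tunnel mouth; normalised
#'   internally.
#' @param radius cut-out radius R_R in Angstrom (default 70).
#' @return an object of class `tunnel_frame`.
#' @export
tunnel_frame <- function(origin, axis, radius = 70) {
  origin <- as.numeric(origin)
  axis <- as.numeric(axis)
  if (length(origin) != 3 || any(!is.finite(origin)))
    abort("`origin` must be a finite length-3 vector")
  if (length(axis) != 3) abort("`axis` must be length 3")
  if (!is.numeric(radius) || radius <= 0) abort("`radius` must be positive")
  structure(list(origin = origin, axis = .unit(axis), radius = radius,
                 hint = FALSE),
            class = "tunnel_frame")
}

#' @export
print.tunnel_frame <- function(x, ...) {
  cat(sprintf("<tunnel_frame>%s origin (%.2f, %.2f, %.2f), axis (%.3f, %.3f, %.3f), R_R = %g A\n",
              if (isTRUE(x$hint)) " [hint]" else "",
              x$origin[1], x$origin[2], x$origin[3],
              x$axis[1], x$axis[2], x$axis[3], x$radius))
  invisible(x)
}

#' Extract the cylindrical cut-out around the exit tunnel
#'
#' Keeps atoms with radial distance from the tunnel axis at most the
#' frame's radius and axial coordinate z >= 0 (the half-space starting at
#' the PTC plane), and re-expresses their coordinates in the tunnel frame
#' (PTC at the origin, axis along +z). A 1e-6 A tolerance keeps boundary
#' atoms.
#'
#' @param atoms an `atomset`.
#' @param frame a `tunnel_frame`.
#' @return an object of class `ribosome_cutout`: the transformed atom table
#'   plus kept/total counts and the frame.
#' @export
extract_cutout <- function(atoms, frame) {
  stopifnot(inherits(frame, "tunnel_frame"))
  if (!nrow(atoms)) abort("empty atomset")
  B <- .frame_basis(frame$axis)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  loc <- sweep(xyz, 2, frame$origin) %*% t(B)
  tol <- 1e-6
  keep <- sqrt(loc[, 1]^2 + loc[, 2]^2) <= frame$radius + tol &
    loc[, 3] >= -tol
  if (!any(keep))
    abort("no atoms fall inside the cut-out; is the tunnel frame correct?")
  at <- atoms[keep, , drop = FALSE]
  at$x <- loc[keep, 1]; at$y <- loc[keep, 2]; at$z <- loc[keep, 3]
  structure(list(atoms = as_tibble(at), n_kept = sum(keep),
                 n_total = nrow(atoms), frame = frame),
            class = "ribosome_cutout")
}

#' @export
print.ribosome_cutout <- function(x, ...) {
  cat(sprintf("<ribosome_cutout> %d of %d atoms kept (R_R = %g A, z >= 0)\n",
              x$n_kept, x$n_total, x$frame$radius))
  invisible(x)
}

#' Advisory PTC frame from the L4/L22 protein chains
#'
#' The constriction formed by the L4 and L22 proteins flanks the upper exit
#' tunnel, so a rough PTC frame can be guessed from them: the origin is the
#' midpoint of the mutually closest atom pair of the two chains, and the
#' axis points from the structure's centre of mass through that midpoint
#' (sign resolved toward the emptier half-space). This is a hint only; the
#' canonical workflow supplies a curated frame.
#'
#' @param atoms an `atomset` containing both chains.
#' @param l4_chain,l22_chain chain identifiers.
#' @param radius cut-out radius for the returned frame.
#' @return a `tunnel_frame` flagged as a hint.
#' @export
locate_ptc_hint <- function(atoms, l4_chain, l22_chain, radius = 70) {
  a4 <- atoms[atoms$chain == l4_chain, , drop = FALSE]
  a22 <- atoms[atoms$chain == l22_chain, , drop = FALSE]
  if (!nrow(a4)) abort(paste0("chain not found: ", l4_chain))
  if (!nrow(a22)) abort(paste0("chain not found: ", l22_chain))
  x4 <- cbind(a4$x, a4$y, a4$z)
  x22 <- cbind(a22$x, a22$y, a22$z)
  # mutually closest atom pair (block over the smaller chain)
  best <- c(Inf, 1L, 1L)
  for (i in seq_len(nrow(x4))) {
    d2 <- (x22[, 1] - x4[i, 1])^2 + (x22[, 2] - x4[i, 2])^2 +
      (x22[, 3] - x4[i, 3])^2
    j <- which.min(d2)
    if (d2[j] < best[1]) best <- c(d2[j], i, j)
  }
  origin <- (x4[best[2], ] + x22[best[3], ]) / 2
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  com <- colMeans(xyz)
  dir <- origin - com
  if (sqrt(sum(dir^2)) < 1) {
    # symmetric case: pick the axis of least atom density
    dir <- .unit(x22[best[3], ] - x4[best[2], ])
    dir <- .frame_basis(dir)[1, ]
  }
  dir <- .unit(dir)
  proj <- sweep(xyz, 2, origin) %*% dir
  if (sum(proj > 0) > sum(proj < 0)) dir <- -dir
  fr <- tunnel_frame(origin, dir, radius)
  fr$hint <- TRUE
  fr
}

#' Build a Calpha native model with an overlap-criterion contact map
#'
#' Residues i and j with |i - j| >= `min_sep` form a native contact iff any
#' pair of their heavy atoms overlaps once the van der Waals spheres are
#' multiplied by `scale`; the contact's native distance is the Calpha-Calpha
#' distance. Formal charges are assigned ASP/GLU = -1 and LYS/ARG = +1
#' (histidine neutral).
#'
#' @param atoms an `atomset` (or a path passed through [load_structure()]).
#' @param chain chain to model; default: the first protein chain.
#' @param scale van der Waals enlargement factor (default 1.24).
#' @param min_sep minimum sequence separation of a contact (default 3).
#' @param vdw_table optional named radius table, see [vdw_radii()].
#' @return an object of class `native_model`: one-letter `sequence`, `xyz`
#'   Calpha coordinates, per-residue `charge`, and a `contacts` tibble with
#'   columns i, j, r_nat.
#' @export
build_native_model <- function(atoms, chain = NULL, scale = 1.24,
                               min_sep = 3, vdw_table = NULL) {
  if (is.character(atoms)) atoms <- load_structure(atoms)
  prot <- atoms[atoms$kind == "protein" & !atoms$het, , drop = FALSE]
  if (!nrow(prot)) abort("no protein atoms in structure")
  chain <- chain %||% prot$chain[1]
  prot <- prot[prot$chain == chain, , drop = FALSE]
  if (!nrow(prot)) abort(paste0("no protein atoms in chain ", chain))
  resno <- unique(prot$resno)
  ca <- prot[prot$atom == "CA", , drop = FALSE]
  missing_ca <- setdiff(resno, ca$resno)
  if (length(missing_ca))
    abort(paste0("residues without a Calpha atom: ",
                 paste(head(missing_ca, 10), collapse = ", ")))
  ca <- ca[match(resno, ca$resno), , drop = FALSE]
  heavy <- prot[prot$element != "H", , drop = FALSE]
  contacts <- cpp_overlap_contacts(
    as.matrix(heavy[, c("x", "y", "z")]),
    vdw_radii(heavy$element, vdw_table),
    as.integer(heavy$resno),
    as.matrix(ca[, c("x", "y", "z")]),
    as.integer(ca$resno), as.integer(min_sep), scale)
  seq1 <- unname(.aa3[ca$resname])
  seq1[is.na(seq1)] <- "X"
  structure(list(
    sequence = seq1,
    xyz = unname(as.matrix(ca[, c("x", "y", "z")])),
    charge = .residue_charge(ca$resname),
    resno = resno,
    contacts = as_tibble(contacts),
    scale = scale, min_sep = min_sep, chain = chain),
    class = "native_model")
}

#' Construct a native model directly from Calpha coordinates
#'
#' Contacts are assigned by a Calpha-distance cutoff; used for synthetic
#' traces that have no side-chain atoms (the production path for real
#' structures is the all-atom overlap criterion in [build_native_model()]).
#'
#' @param xyz n x 3 Calpha coordinates (Angstrom).
#' @param cutoff contact distance cutoff (Angstrom, default 7.5).
#' @param min_sep minimum sequence separation (default 3).
#' @param sequence,charge optional per-residue annotations.
#' @return a `native_model`.
#' @export
native_model_from_ca <- function(xyz, cutoff = 7.5, min_sep = 3,
                                 sequence = NULL, charge = NULL) {
  .assert_matrix3(xyz, "xyz")
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  keep <- (idx[, 2] - idx[, 1]) >= min_sep
  idx <- idx[keep, , drop = FALSE]
  structure(list(
    sequence = sequence %||% rep("A", n),
    xyz = unname(xyz),
    charge = as.integer(charge %||% rep(0L, n)),
    resno = seq_len(n),
    contacts = tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                      r_nat = d[idx]),
    scale = NA_real_, min_sep = min_sep, chain = "A"),
    class = "native_model")
}

#' @export
print.native_model <- function(x, ...) {
  cat(sprintf("<native_model> %d residues, %d native contacts (min_sep %d)\n",
              length(x$sequence), nrow(x$contacts), x$min_sep))
  invisible(x)
}

#' @rdname tidy-ribotunnel
#' @export
tidy.native_model <- function(x, ...) as_tibble(x$contacts)

#' @rdname glance-ribotunnel
#' @export
glance.native_model <- function(x, ...) {
  tibble(n_residues = length(x$sequence), n_contacts = nrow(x$contacts),
         min_sep = x$min_sep, mean_r_nat = mean(x$contacts$r_nat))
}

#' Write a native model as a contact-map TSV and a FASTA record
#'
#' @param model a `native_model`.
#' @param contacts_path,fasta_path output paths (either may be NULL to skip).
#' @param name FASTA record name.
#' @return invisibly, the model.
#' @export
write_native_model <- function(model, contacts_path = NULL,
                               fasta_path = NULL, name = "native") {
  if (!is.null(contacts_path)) {
    con <- model$contacts
    names(con) <- c("i", "j", "r_nat")
    utils::write.table(con, contacts_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(fasta_path)) {
    writeLines(c(paste0(">", name),
                 paste(model$sequence, collapse = "")), fasta_path)
  }
  invisible(model)
}

#' Write a cut-out (or any atomset) as a PDB fragment
#'
#' Coordinates are written as they are stored; for a `ribosome_cutout` that
#' is the tunnel frame (PTC at the origin, axis = +z).
#'
#' @param x a `ribosome_cutout` or `atomset`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cutout_pdb <- function(x, path) {
  at <- if (inherits(x, "ribosome_cutout")) x$atoms else x
  n <- nrow(at)
  ser <- ((seq_len(n) - 1L) %% 99999L) + 1L
  resno <- ((at$resno - 1L) %% 9999L) + 1L
  lines <- sprintf(
    "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(at$het, "HETATM", "ATOM"), ser,
    substr(at$atom, 1, 4), substr(at$resname, 1, 3),
    substr(ifelse(is.na(at$chain), "X", at$chain), 1, 1),
    resno, at$x, at$y, at$z, 1, 0, substr(at$element, 1, 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
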