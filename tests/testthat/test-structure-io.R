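# structure parsing, tunnel frame, cylindrical cut-out, native models

test_that("hand-written PDB records round-trip bit-exactly", {
  pdb <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "HETATM    3  O   HOH B   9       1.500  -2.250   0.125  1.00  0.00           O",
    "END")
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, tf)
  at <- load_structure(tf)
  expect_s3_class(at, "atomset")
  expect_equal(nrow(at), 3)
  expect_identical(at$x, c(11.104, 11.639, 1.500))
  expect_identical(at$z, c(-6.504, -5.147, 0.125))
  expect_identical(at$kind, c("protein", "protein", "other"))
  expect_identical(at$het, c(FALSE, FALSE, TRUE))
})

test_that("unparsable and empty files raise clean errors", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", tf)
  expect_error(load_structure(tf), "parse|atom")
  expect_error(load_structure("/nonexistent/file.pdb"), "not found")
})

test_that("cut-out equals a brute-force cylinder filter and is idempotent", {
  set.seed(3)
  pts <- matrix(runif(3e4, -90, 90), ncol = 3)
  as <- atomset(pts)
  fr <- tunnel_frame(c(5, -3, 2), c(0.3, 0.2, 0.9), radius = 40)
  cut <- extract_cutout(as, fr)
  B <- ribotunnel:::.frame_basis(fr$axis)
  loc <- sweep(pts, 2, fr$origin) %*% t(B)
  keep <- sqrt(loc[, 1]^2 + loc[, 2]^2) <= 40 + 1e-6 & loc[, 3] >= -1e-6
  expect_equal(cut$n_kept, sum(keep))
  expect_equal(unname(cbind(cut$atoms$x, cut$atoms$y, cut$atoms$z)),
               unname(loc[keep, , drop = FALSE]))
  # idempotence: re-extracting in the tunnel frame keeps everything
  fr0 <- tunnel_frame(c(0, 0, 0), c(0, 0, 1), radius = 40)
  cut2 <- extract_cutout(cut$atoms, fr0)
  expect_equal(cut2$n_kept, cut$n_kept)
  # all atoms on the axis with z >= 0 are kept
  onax <- atomset(cbind(0, 0, seq(0, 50, by = 5)))
  expect_equal(extract_cutout(onax, fr0)$n_kept, 11)
  # frame misplaced -> empty cut-out error
  expect_error(
    extract_cutout(atomset(cbind(0, 0, -(1:10))), fr0), "no atoms")
})

test_that("overlap criterion reproduces direct sphere arithmetic", {
  # CB pair 3.0 A apart: 3.0 < 1.24 * (1.7 + 1.7) = 4.216 -> contact
  m <- build_native_model(dipeptide_atomset(3.0), min_sep = 3)
  expect_equal(nrow(m$contacts), 1)
  expect_equal(m$contacts$i, 1L)
  expect_equal(m$contacts$j, 5L)
  # r_nat is the Calpha-Calpha distance, not the CB-CB distance
  expect_equal(m$contacts$r_nat, 3.0, tolerance = 1e-12)
  # same pair at 4.3 A: 4.3 > 4.216 -> no contact
  expect_equal(nrow(build_native_model(dipeptide_atomset(4.3),
                                       min_sep = 3)$contacts), 0)
  # residues 50 A apart never touch
  expect_equal(nrow(build_native_model(dipeptide_atomset(50),
                                       min_sep = 3)$contacts), 0)
  # adjacent residues excluded by min_sep even when overlapping
  expect_equal(nrow(build_native_model(dipeptide_atomset(3.0),
                                       min_sep = 5)$contacts), 0)
})

test_that("contact map is invariant under rigid motion", {
  at <- dipeptide_atomset(3.0)
  set.seed(7)
  R <- ribotunnel:::.random_rotation()
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at2 <- at
  at2$x <- xyz[, 1] + 13.2; at2$y <- xyz[, 2] - 8; at2$z <- xyz[, 3] + 4
  m1 <- build_native_model(at, min_sep = 3)
  m2 <- build_native_model(at2, min_sep = 3)
  expect_equal(m1$contacts$i, m2$contacts$i)
  expect_equal(m1$contacts$j, m2$contacts$j)
  expect_equal(m1$contacts$r_nat, m2$contacts$r_nat, tolerance = 1e-9)
})

test_that("charges follow residue identity with neutral histidine", {
  at <- dipeptide_atomset(3.0)
  at$resname[at$resno == 1] <- "ASP"
  at$resname[at$resno == 2] <- "LYS"
  at$resname[at$resno == 3] <- "HIS"
  m <- build_native_model(at, min_sep = 3)
  expect_identical(m$charge, c(-1L, 1L, 0L, 0L, 0L))
})

test_that("missing Calpha atoms are reported", {
  at <- dipeptide_atomset(3.0)
  at <- at[!(at$resno == 3 & at$atom == "CA"), ]
  expect_error(build_native_model(at, min_sep = 3), "Calpha")
})

test_that("PTC hint lands near constructed two-blob geometry", {
  set.seed(5)
  blob <- function(center, chain, n = 200, sd = 3) {
    atomset(matrix(rnorm(3 * n, sd = sd), ncol = 3) +
              matrix(center, n, 3, byrow = TRUE), chain = chain,
            resname = "ALA")
  }
  # bulk mass below; L4/L22 blobs carry deterministic innermost tip atoms
  # at (-3, 0, 20) and (3, 0, 20), so the constructed origin is (0, 0, 20)
  bulk <- blob(c(0, 0, -30), "B", 2000)
  l4 <- dplyr::bind_rows(blob(c(-14, 0, 20), "4"),
                         atomset(rbind(c(-3, 0, 20)), chain = "4",
                                 resname = "ALA"))
  l22 <- dplyr::bind_rows(blob(c(14, 0, 20), "2"),
                          atomset(rbind(c(3, 0, 20)), chain = "2",
                                  resname = "ALA"))
  at <- dplyr::bind_rows(bulk, l4, l22)
  class(at) <- c("atomset", class(tibble::tibble()))
  fr <- locate_ptc_hint(at, "4", "2")
  expect_true(fr$hint)
  expect_lt(sqrt(sum((fr$origin - c(0, 0, 20))^2)), 2)
  # axis points away from the bulk (toward +z)
  expect_gt(fr$axis[3], 0.7)
  expect_error(locate_ptc_hint(at, "4", "Z"), "chain")
})

test_that("native model writers emit contact TSV and FASTA", {
  m <- build_native_model(dipeptide_atomset(3.0), min_sep = 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_native_model(m, tsv, fa, name = "dipep")
  con <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(con$i, 1)
  expect_equal(con$r_nat, 3, tolerance = 1e-6)
  expect_identical(readLines(fa), c(">dipep", "AAAAA"))
})
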