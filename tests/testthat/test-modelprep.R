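test_that("PDB fixtures round-trip through read and write", {
  path <- write_pdb_fixture(c(0.50, 0.80, 0.65))
  m <- read_model(path, mode = "delta")
  expect_s3_class(m, "predicted_model")
  expect_equal(residue_delta <- residue_table(m)$delta, c(0.50, 0.80, 0.65))
  expect_equal(m$cell$a, 30)
  out <- tempfile(fileext = ".pdb")
  write_model(m, out, b_policy = "original")
  m2 <- read_model(out, mode = "delta")
  expect_equal(m2$atoms[, c("x", "y", "z", "occ", "b")],
               m$atoms[, c("x", "y", "z", "occ", "b")])
  expect_equal(m2$atoms$resid, m$atoms$resid)
})

test_that("read_model agrees with the bio3d parser on coordinates and B", {
  path <- write_pdb_fixture(c(1.2, 0.3, 2.5, 0.9))
  m <- read_model(path, mode = "delta")
  ref <- bio3d::read.pdb(path, verbose = FALSE)
  expect_equal(m$atoms$x, ref$atom$x)
  expect_equal(m$atoms$y, ref$atom$y)
  expect_equal(m$atoms$z, ref$atom$z)
  expect_equal(m$atoms$b, ref$atom$b)
  expect_equal(m$atoms$resid, ref$atom$resno)
})

test_that("parse errors name the offending line", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.50           C",
    "ATOM      2  CA  ALA A   2       4.0"), path)
  expect_error(read_model(path, "delta"), "line 2")
  writeLines("REMARK nothing here", path)
  expect_error(read_model(path, "delta"), "no ATOM records")
})

test_that("B-column interpretation modes behave as documented", {
  path <- write_pdb_fixture(c(90, 70, 45))  # pLDDT-scale values
  mp <- read_model(path, "plddt")
  d <- residue_table(mp)$delta
  expect_equal(d, plddt_to_delta(c(90, 70, 45)))
  expect_true(all(diff(d) > 0))  # lower pLDDT, larger error
  mb <- read_model(path, "plain-b")
  expect_true(all(is.na(mb$atoms$delta)))
  expect_error(trim_by_error(mb, 1), "plain-b")
})

test_that("the error-to-B conversion is exactly 8 pi^2 delta^2 / 3", {
  expect_identical(error_to_bfactor(0), 0)
  expect_equal(error_to_bfactor(1), 8 * pi^2 / 3)
  expect_equal(error_to_bfactor(1), 26.3189, tolerance = 1e-4)
  d <- c(0.3, 0.7, 1.4, 2.2)
  expect_equal(error_to_bfactor(2 * d), 4 * error_to_bfactor(d))
  expect_true(all(diff(error_to_bfactor(seq(0, 3, by = 0.1))) > 0))
  expect_error(error_to_bfactor(-0.2), "delta")
})

test_that("error-threshold trimming applies the per-residue rule", {
  path <- write_pdb_fixture(c(0.5, 0.8, 0.65))
  m <- read_model(path, "delta")
  t1 <- trim_by_error(m, 0.7)
  expect_equal(unique(t1$atoms$resid), c(1L, 3L))
  expect_equal(attr(t1, "retained_fraction"), 2 / 3)
  # idempotence and identity above the max error
  expect_equal(trim_by_error(t1, 0.7)$atoms, t1$atoms)
  expect_equal(trim_by_error(m, 5)$atoms, m$atoms)
  expect_error(trim_by_error(m, 0.1), "every residue")
  expect_error(trim_by_error(m, -1), "positive")
})

test_that("larger trimming thresholds retain supersets of residues", {
  set.seed(8)
  deltas <- runif(40, 0.2, 2.0)
  m <- read_model(write_pdb_fixture(deltas), "delta")
  kept <- lapply(c(0.7, 1.0, 1.2), function(th) unique(trim_by_error(m, th)$atoms$resid))
  expect_true(all(kept[[1]] %in% kept[[2]]))
  expect_true(all(kept[[2]] %in% kept[[3]]))
  expect_setequal(kept[[2]], which(deltas <= 1.0))
})

test_that("ensemble divergence trimming removes exactly the divergent residues", {
  path <- write_pdb_fixture(rep(0.5, 50))
  m1 <- read_model(path, "delta")
  m2 <- read_model(path, "delta")
  ens <- ensemble(m1, m2)
  same <- ensemble_divergence_trim(ens, 0.01)
  expect_equal(nrow(same[[1]]$atoms), nrow(m1$atoms))

  # displace residue 4 of member 2 by 2 A; at a 0.1 A threshold it must go
  m2b <- read_model(path, "delta")
  rows <- m2b$atoms$resid == 4
  m2b$atoms$x[rows] <- m2b$atoms$x[rows] + 2
  trimmed <- ensemble_divergence_trim(ensemble(m1, m2b), 0.1)
  expect_setequal(unique(trimmed[[1]]$atoms$resid), setdiff(1:50, 4))
  expect_setequal(unique(trimmed[[2]]$atoms$resid), setdiff(1:50, 4))
  # brute-force divergence check: only residue 4 exceeds the threshold
  div <- attr(trimmed, "divergence")
  expect_gt(div[["A 4"]], 1.5)
  expect_true(all(div[names(div) != "A 4"] <= 0.1))
  expect_error(ensemble(m1), "at least 2")
})

test_that("fm estimation is a scattering fraction, not an atom count", {
  path100 <- write_pdb_fixture(rep(0.5, 100))
  path80 <- write_pdb_fixture(rep(0.5, 80))
  full <- read_model(path100, "delta")
  part <- read_model(path80, "delta")
  asu <- sum((full$atoms$occ * scattering_factor(full$atoms$element))^2)
  expect_equal(estimate_fm(part, asu), 0.8)
  # one copy modelled of two in the asymmetric unit
  expect_equal(estimate_fm(full, 2 * asu), 0.5)
  expect_error(estimate_fm(full, asu / 2), "exceeds")

  # mixed elements: the naive atom-count ratio is wrong, the sum(f^2) is right
  mixed <- full
  mixed$atoms$element[1:50] <- "S"
  f2 <- scattering_factor(mixed$atoms$element)^2
  oracle <- sum(f2[1:120]) / sum(f2)
  got <- local({
    sub <- mixed; sub$atoms <- sub$atoms[1:120, ]
    estimate_fm(sub, sum((mixed$atoms$occ * scattering_factor(mixed$atoms$element))^2))
  })
  expect_equal(got, oracle)
  expect_false(isTRUE(all.equal(oracle, 120 / 200)))
})

test_that("trimming cannot increase the scattering fraction", {
  deltas <- seq(0.3, 1.8, length.out = 20)
  m <- read_model(write_pdb_fixture(deltas), "delta")
  asu <- 2 * sum((m$atoms$occ * scattering_factor(m$atoms$element))^2)
  expect_lte(estimate_fm(trim_by_error(m, 1.0), asu), estimate_fm(m, asu))
})

test_that("write_model's delta-converted policy writes B = 8 pi^2 delta^2/3", {
  m <- read_model(write_pdb_fixture(c(1.0, 0.5)), "delta")
  out <- tempfile(fileext = ".pdb")
  write_model(m, out, b_policy = "delta-converted")
  lines <- grep("^ATOM", readLines(out), value = TRUE)
  expect_equal(substr(lines[1], 61, 66), " 26.32")
  back <- read_model(out, "plain-b")
  expect_equal(back$atoms$b[1], 26.32)
  m$atoms <- m$atoms[0, , drop = FALSE]
  expect_error(write_model(m, out), "empty")
})

test_that("sequence scattering totals follow the composition table", {
  # glycine: C2 N O -> 2*36 + 49 + 64 = 185
  expect_equal(sequence_scattering("G"), 185)
  expect_equal(sequence_scattering("GG"), 370)
  expect_equal(sequence_scattering("G", copies = 3), 555)
  # cysteine adds one sulfur (256)
  expect_equal(sequence_scattering("C") - sequence_scattering("A"), 256)
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">seq", "GAG"), fa)
  expect_equal(sequence_scattering(fa),
               2 * sequence_scattering("G") + sequence_scattering("A"))
  expect_error(sequence_scattering("GXZ"), "unknown residue")
})
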