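# Shared fixture builders and independent oracles for the test suite.

# Ideal alpha-helix CA trace: radius 2.3 A, rise 1.5 A, twist 100 deg.
make_helix <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  i <- seq_len(n) - 1
  om <- twist * pi / 180
  cbind(radius * cos(i * om), radius * sin(i * om), i * rise)
}

# Rotation matrix about a unit axis by angle (degrees), Rodrigues form.
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Helix of 2*half residues with a kink of `angle_deg` at the midpoint.
make_kinked_helix <- function(half = 14, angle_deg = 25) {
  ca <- make_helix(2 * half)
  R <- rotation_about(c(1, 0, 0), angle_deg)
  pivot <- ca[half, ]
  idx <- (half + 1):(2 * half)
  ca[idx, ] <- sweep(sweep(ca[idx, , drop = FALSE], 2, pivot) %*% t(R), 2, -pivot)
  ca
}

# Random proper rotation (QR of a Gaussian matrix, det fixed to +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Build a reflection_set by hand from explicit indices (P1 flags).
make_refl <- function(cell, hkl) {
  hkl <- rbind(hkl)
  df <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                   d = d_spacing(cell, hkl), centric = FALSE, epsilon = 1L)
  structure(df, class = c("reflection_set", "data.frame"),
            cell = cell, dmin = min(df$d), symops = space_group_ops("P1"))
}

# Independent direct-summation structure-factor oracle: explicit scalar
# accumulation per reflection and atom, no vectorized shortcuts.
sf_reference_loop <- function(model, reflections) {
  f <- scattering_factor(model$element)
  out <- complex(nrow(reflections))
  for (r in seq_len(nrow(reflections))) {
    s2 <- 1 / reflections$d[r]^2
    acc <- 0 + 0i
    for (j in seq_len(nrow(model))) {
      ph <- 2 * pi * (reflections$h[r] * model$xf[j] +
                        reflections$k[r] * model$yf[j] +
                        reflections$l[r] * model$zf[j])
      w <- model$occ[j] * f[j] * exp(-model$b[j] * s2 / 4)
      acc <- acc + w * complex(real = cos(ph), imaginary = sin(ph))
    }
    out[r] <- acc
  }
  out
}

# Random atomic model with arbitrary elements/occupancies/B for oracles.
random_test_model <- function(n_atoms, cell, b_range = c(0, 30)) {
  atomic_model(data.frame(
    chain = "A", resid = seq_len(n_atoms), resname = "ALA", atom = "CA",
    element = sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE),
    xf = runif(n_atoms), yf = runif(n_atoms), zf = runif(n_atoms),
    occ = runif(n_atoms, 0.5, 1), b = runif(n_atoms, b_range[1], b_range[2]),
    stringsAsFactors = FALSE), cell)
}

# Write a minimal PDB fixture with given per-residue B values (one CA + one
# CB atom per residue) and return its path.
write_pdb_fixture <- function(bvals, path = tempfile(fileext = ".pdb"),
                              cell_line = TRUE) {
  lines <- character(0)
  if (cell_line) {
    lines <- "CRYST1   30.000   40.000   50.000  90.00  90.00  90.00 P 1           1"
  }
  serial <- 0
  for (i in seq_along(bvals)) {
    for (at in c("CA", "CB")) {
      serial <- serial + 1
      el <- "C"
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, at, i, i * 3.8, 2 * sin(i) + (at == "CB"), 2 * cos(i), 1.00,
        bvals[i], el))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# Simulated crystal + data used by several likelihood tests.
sim_crystal_data <- function(n_res = 60, dmin = 3.0, rmsd = 0.8, fm = 1,
                             seed = 7, cell_edge = 30) {
  cell <- unit_cell(cell_edge, cell_edge, cell_edge)
  refl <- generate_reflections(cell, space_group_ops("P1"), dmin = dmin)
  pair <- simulate_pair(n_res, cell, rmsd = rmsd, fm = fm, seed = seed)
  e_obs <- normalize_e(calc_structure_factors(pair$target, refl))$e
  e_calc <- normalize_e(calc_structure_factors(pair$model, refl))$e
  list(cell = cell, refl = refl, pair = pair, e_obs = e_obs, e_calc = e_calc)
}
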