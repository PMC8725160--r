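test_that("structure factors of trivial arrangements are exact", {
  cell <- unit_cell(10, 10, 10)
  refl <- generate_reflections(cell, dmin = 4)
  one <- atomic_model(data.frame(
    chain = "A", resid = 1, resname = "ALA", atom = "CA", element = "C",
    xf = 0, yf = 0, zf = 0, occ = 1, b = 0), cell)
  sf <- calc_structure_factors(one, refl)
  expect_equal(sf$amp, rep(scattering_factor("C"), nrow(refl)))

  two <- atomic_model(data.frame(
    chain = "A", resid = 1:2, resname = "ALA", atom = "CA", element = "C",
    xf = c(0, 0.5), yf = 0, zf = 0, occ = 1, b = 0), cell)
  sf2 <- calc_structure_factors(two, make_refl(cell, c(1, 0, 0)))
  expect_equal(sf2$amp, 0, tolerance = 1e-10)

  bad_cell_refl <- generate_reflections(unit_cell(11, 10, 10), dmin = 4)
  expect_error(calc_structure_factors(one, bad_cell_refl), "same unit cell")
})

test_that("the vectorized engine equals an independent per-atom loop", {
  set.seed(42)
  for (i in 1:20) {
    cell <- unit_cell(runif(1, 10, 20), runif(1, 10, 20), runif(1, 10, 20),
                      runif(1, 80, 100), runif(1, 80, 100), runif(1, 80, 100))
    refl <- generate_reflections(cell, dmin = 4)
    model <- random_test_model(sample(10:50, 1), cell)
    sf <- calc_structure_factors(model, refl)
    ref <- sf_reference_loop(model, refl)
    expect_equal(sf$f, ref, tolerance = 1e-10)
  }
})

test_that("Friedel mates are complex conjugates", {
  cell <- unit_cell(14, 16, 18, 92, 88, 95)
  model <- random_test_model(30, cell)
  hkl <- rbind(c(1, 2, 3), c(2, -1, 0), c(0, 3, -2))
  plus <- calc_structure_factors(model, make_refl(cell, hkl))
  minus <- calc_structure_factors(model, make_refl(cell, -hkl))
  expect_equal(minus$f, Conj(plus$f), tolerance = 1e-12)
})

test_that("Wilson Sigma-N follows its defining sum", {
  cell <- unit_cell(25, 25, 25)
  refl <- generate_reflections(cell, dmin = 3)
  model <- random_test_model(40, cell, b_range = c(0, 0))
  sn <- wilson_sigma_n(model, refl, shells = 5)
  f <- scattering_factor(model$element)
  expect_equal(sn$sigma_n, rep(sum((model$occ * f)^2), 5))

  half <- model; half$occ <- half$occ / 2
  sn_half <- wilson_sigma_n(atomic_model(half, cell), refl, shells = 5)
  expect_equal(sn_half$sigma_n, sn$sigma_n / 4)
})

test_that("mean intensity per shell matches Wilson statistics on random atoms", {
  cell <- unit_cell(30, 30, 30)
  refl <- generate_reflections(cell, dmin = 3)  # > 2000 reflections, one shell
  set.seed(99)
  model <- random_test_model(300, cell, b_range = c(0, 0))
  sf <- calc_structure_factors(model, refl)
  sn <- wilson_sigma_n(model, refl, shells = 1)
  expect_equal(mean(sf$amp^2 / sf$epsilon), sn$sigma_n, tolerance = 0.05)
})

test_that("empirical E-normalization gives unit mean E^2, scale-invariantly and idempotently", {
  cell <- unit_cell(28, 28, 28)
  refl <- generate_reflections(cell, dmin = 3)
  model <- random_test_model(150, cell)
  sf <- calc_structure_factors(model, refl)
  norm1 <- normalize_e(sf, shells = 8)
  idx <- attr(norm1, "shell")
  for (sh in unique(idx)) {
    expect_equal(mean(norm1$e[idx == sh]^2 * 1), 1, tolerance = 1e-9)
  }
  scaled <- sf; scaled$amp <- scaled$amp * 10
  expect_equal(normalize_e(scaled, shells = 8)$e, norm1$e, tolerance = 1e-12)
  # idempotence: treating E as amplitudes and renormalizing changes nothing
  again <- norm1; again$amp <- norm1$e
  expect_equal(normalize_e(again, shells = 8)$e, norm1$e, tolerance = 1e-12)
  expect_error(normalize_e(sf[1:4, ], shells = 8), "fewer reflections than shells")
})

test_that("theoretical and empirical normalization agree on large random models", {
  cell <- unit_cell(30, 30, 30)
  refl <- generate_reflections(cell, dmin = 3)
  set.seed(5)
  model <- random_test_model(400, cell, b_range = c(0, 0))
  sf <- calc_structure_factors(model, refl)
  emp <- normalize_e(sf, shells = 4)
  theo <- normalize_e(sf, shells = 4, mode = "theoretical", model = model)
  idx <- attr(emp, "shell")
  for (sh in unique(idx)) {
    ratio <- mean(theo$e[idx == sh]^2) / mean(emp$e[idx == sh]^2)
    expect_equal(ratio, 1, tolerance = 0.1)
  }
})

test_that("acentric normalized intensities show Wilson moments", {
  cell <- unit_cell(30, 30, 30)
  refl <- generate_reflections(cell, dmin = 3)
  pair <- simulate_pair(100, cell, rmsd = 0, fm = 1, seed = 17)
  e <- normalize_e(calc_structure_factors(pair$target, refl), shells = 4)$e
  expect_equal(mean(e^4), 2, tolerance = 0.15)  # <E^4> = 2 for acentric Wilson
})

test_that("simulated pairs honour the requested rmsd, fm and seed exactly", {
  cell <- unit_cell(30, 30, 30)
  pair <- simulate_pair(40, cell, rmsd = 0.8, fm = 1, seed = 7)
  expect_equal(nrow(pair$model), nrow(pair$target))
  ot <- frac_to_orth(cell, as.matrix(pair$target[, c("xf", "yf", "zf")]))
  om <- frac_to_orth(cell, as.matrix(pair$model[, c("xf", "yf", "zf")]))
  expect_equal(sqrt(mean(rowSums((om - ot)^2))), 0.8, tolerance = 1e-9)

  part <- simulate_pair(40, cell, rmsd = 0.5, fm = 0.6, seed = 7)
  idx <- attr(part$model, "target_index")
  f2 <- (part$target$occ * scattering_factor(part$target$element))^2
  fm_real <- sum(f2[idx]) / sum(f2)
  expect_equal(fm_real, 0.6, tolerance = 0.05)
  ot <- frac_to_orth(cell, as.matrix(part$target[idx, c("xf", "yf", "zf")]))
  om <- frac_to_orth(cell, as.matrix(part$model[, c("xf", "yf", "zf")]))
  expect_equal(sqrt(mean(rowSums((om - ot)^2))), 0.5, tolerance = 1e-9)

  again <- simulate_pair(40, cell, rmsd = 0.8, fm = 1, seed = 7)
  expect_identical(pair, again)
  other <- simulate_pair(40, cell, rmsd = 0.8, fm = 1, seed = 8)
  expect_false(isTRUE(all.equal(pair$model$xf, other$model$xf)))
  expect_error(simulate_pair(40, cell, rmsd = 0.8, fm = 0, seed = 1), "fm")
})

test_that("observed-amplitude simulation applies the stated noise model", {
  cell <- unit_cell(30, 30, 30)
  refl <- generate_reflections(cell, dmin = 2.2)
  pair <- simulate_pair(50, cell, rmsd = 0, fm = 1, seed = 2)
  sf <- calc_structure_factors(pair$target, refl)
  expect_identical(simulate_observed(sf, 0), sf$amp)
  obs <- simulate_observed(sf, 0.05, seed = 4)
  expect_gt(nrow(sf), 5000)
  rel <- sd((obs - sf$amp) / sf$amp)
  expect_equal(rel, 0.05, tolerance = 0.1)
  expect_identical(obs, simulate_observed(sf, 0.05, seed = 4))
  expect_error(simulate_observed(sf, -0.1), "noise_fraction")
})
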