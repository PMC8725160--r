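test_that("superposition of identical sets is the identity with zero rmsd", {
  set.seed(1)
  a <- matrix(rnorm(30), 10, 3)
  sp <- superpose(a, a)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  expect_error(superpose(a[1:2, ], a[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
})

test_that("superposition exactly recovers an applied rigid motion", {
  set.seed(2)
  a <- matrix(rnorm(60), 20, 3)
  R <- rotation_about(c(0, 0, 1), 37)
  b <- sweep(a %*% t(R), 2, c(3, -1, 2), "+")
  sp <- superpose(a, b)
  expect_lt(sp$rmsd, 1e-6)
  expect_equal(sp$rotation, t(R), tolerance = 1e-9)
  expect_equal(apply_superposition(sp, a), b, tolerance = 1e-7)
})

test_that("superposition rmsd is invariant to rigid motion of either input", {
  set.seed(3)
  a <- matrix(rnorm(45), 15, 3)
  b <- a + matrix(rnorm(45, sd = 0.5), 15, 3)
  base <- superpose(a, b)$rmsd
  for (i in 1:5) {
    R <- random_rotation()
    t_ <- rnorm(3)
    expect_equal(superpose(sweep(a %*% R, 2, t_, "+"), b)$rmsd, base, tolerance = 1e-9)
    expect_equal(superpose(a, sweep(b %*% R, 2, t_, "+"))$rmsd, base, tolerance = 1e-9)
  }
})

test_that("Kabsch beats a large random-rotation search", {
  set.seed(4)
  a <- matrix(rnorm(90), 30, 3)
  b <- a + matrix(rnorm(90, sd = 0.8), 30, 3)
  best <- superpose(a, b)$rmsd
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  oracle <- Inf
  for (chunk in 1:100) {
    for (i in 1:1000) {
      R <- random_rotation()
      oracle <- min(oracle, sqrt(mean(rowSums((a0 %*% R - b0)^2))))
    }
  }
  expect_lte(best, oracle)
})

test_that("superposition matches the bio3d least-squares fit", {
  set.seed(5)
  a <- matrix(rnorm(60), 20, 3)
  b <- a %*% random_rotation() + matrix(rnorm(60, sd = 0.4), 20, 3)
  sp <- superpose(a, b)
  xyz <- bio3d::fit.xyz(fixed = as.vector(t(b)), mobile = as.vector(t(a)),
                        fixed.inds = 1:60, mobile.inds = 1:60)
  ref_rmsd <- sqrt(mean(rowSums((matrix(xyz, ncol = 3, byrow = TRUE) - b)^2)))
  expect_equal(sp$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("GDT is exact on hand-countable fixtures", {
  tgt <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(11.4, 0, 0))
  mdl <- tgt
  mdl[2, 3] <- 20  # one atom displaced far beyond every cutoff
  g <- gdt(mdl, tgt, superposition = "identity")
  expect_equal(as.numeric(g), 75)
  expect_equal(unname(attr(g, "per_cutoff")), rep(0.75, 4))
  expect_equal(as.numeric(gdt(tgt, tgt, superposition = "identity")), 100)

  # a single cutoff reduces to plain distance counting
  g1 <- gdt(mdl, tgt, cutoffs = 2, superposition = "identity")
  expect_equal(as.numeric(g1), 100 * 3 / 4)
  expect_error(gdt(tgt[0, , drop = FALSE], tgt[0, , drop = FALSE]), "non-empty")
})

test_that("identical structures score 100 under the GDT search", {
  ca <- make_helix(25)
  expect_equal(as.numeric(gdt_ts(ca, ca)), 100)
  expect_equal(as.numeric(gdt_ha(ca, ca)), 100)
})

test_that("GDT_HA never exceeds GDT_TS", {
  set.seed(6)
  for (i in 1:100) {
    n <- sample(10:25, 1)
    tgt <- make_helix(n) + matrix(rnorm(3 * n, sd = 0.3), n, 3)
    mdl <- tgt + matrix(rnorm(3 * n, sd = runif(1, 0.1, 3)), n, 3)
    expect_lte(as.numeric(gdt_ha(mdl, tgt)), as.numeric(gdt_ts(mdl, tgt)) + 1e-9)
  }
})

test_that("LCS finds the longest fittable window", {
  ca <- make_helix(30)
  expect_equal(as.numeric(lcs(ca, ca, 1)), 100)

  # second half rigidly displaced far away: LCS = 50 at small cutoffs
  tgt <- make_helix(100)
  mdl <- tgt
  mdl[51:100, ] <- mdl[51:100, ] + 50
  expect_equal(as.numeric(lcs(mdl, tgt, 0.5)), 50)
  expect_equal(attr(lcs(mdl, tgt, 0.5), "window"), c(1, 50))
})

test_that("LCS equals the exhaustive window-search oracle", {
  lcs_oracle <- function(a, b, cutoff) {
    n <- nrow(a)
    best <- 0
    for (i in 1:(n - 2)) {
      for (j in (i + 2):n) {
        sp <- superpose(a[i:j, , drop = FALSE], b[i:j, , drop = FALSE])
        if (sp$rmsd <= cutoff) best <- max(best, j - i + 1)
      }
    }
    100 * best / n
  }
  set.seed(7)
  for (rep in 1:4) {
    n <- sample(c(40, 80, 150, 200), 1)
    tgt <- make_helix(n)
    mdl <- tgt + matrix(rnorm(3 * n, sd = runif(1, 0.3, 1.2)), n, 3)
    cutoff <- runif(1, 0.5, 2)
    expect_equal(as.numeric(lcs(mdl, tgt, cutoff)), lcs_oracle(mdl, tgt, cutoff))
  }
})

test_that("LCS is monotone non-decreasing in the cutoff", {
  set.seed(8)
  n <- 60
  tgt <- make_helix(n)
  mdl <- tgt + matrix(rnorm(3 * n, sd = 0.8), n, 3)
  vals <- vapply(c(0.5, 1, 2, 4, 8), function(cc) as.numeric(lcs(mdl, tgt, cc)), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("the LGA_S-style combination is a bounded weighted mean", {
  expect_equal(lga_s(80, 60, weight = 1), 80)
  expect_equal(lga_s(80, 60, weight = 0), 60)
  for (w in seq(0, 1, by = 0.25)) {
    v <- lga_s(73, 91, w)
    expect_gte(v, 73); expect_lte(v, 91)
  }
  expect_error(lga_s(120, 50), "\\[0, 100\\]")
  expect_error(lga_s(50, 50, weight = 2), "weight")
})

test_that("an ideal straight helix is linear with sub-degree bending", {
  h <- helix_axes(make_helix(20))
  expect_lt(h$max_bend, 1)
  expect_equal(h$class, "linear")
  expect_equal(abs(h$axis), c(0, 0, 1), tolerance = 0.02)
  expect_error(helix_axes(make_helix(5)), "too short")
})

test_that("a constructed kink is measured and classified", {
  k25 <- helix_axes(make_kinked_helix(half = 14, angle_deg = 25))
  expect_equal(k25$max_bend, 25, tolerance = 2)
  expect_equal(k25$class, "kinked")

  # the published class boundaries: max bend 7.4 deg falls on the
  # curved-or-linear side, 25.7 deg on the kinked side
  k74 <- helix_axes(make_kinked_helix(half = 14, angle_deg = 7.4))
  expect_true(k74$class %in% c("curved", "linear"))
  k257 <- helix_axes(make_kinked_helix(half = 14, angle_deg = 25.7))
  expect_equal(k257$class, "kinked")
})

test_that("inter-helix angles follow the axis geometry", {
  expect_equal(inter_helix_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(inter_helix_angle(c(0, 0, 1), c(0, 0, -1)), 180)
  h1 <- helix_axes(make_helix(15))
  ca2 <- make_helix(15) %*% t(rotation_about(c(1, 0, 0), 90))
  h2 <- helix_axes(ca2)
  expect_equal(inter_helix_angle(h1$axis, h2$axis), 90, tolerance = 1)
  s1 <- inter_helix_angle(c(0, 0, 1), c(0, 1, 1), mode = "signed", reference = c(1, 0, 0))
  s2 <- inter_helix_angle(c(0, 1, 1), c(0, 0, 1), mode = "signed", reference = c(1, 0, 0))
  expect_equal(s1, -s2)
  expect_error(inter_helix_angle(c(0, 0, 0), c(0, 0, 1)), "zero")
  expect_error(inter_helix_angle(c(0, 0, 1), c(0, 1, 0), mode = "signed"), "reference")
})

test_that("the score report assembles consistent components", {
  set.seed(9)
  n <- 40
  tgt <- make_helix(n)
  mdl <- tgt + matrix(rnorm(3 * n, sd = 0.5), n, 3)
  rep_ <- score_report(mdl, tgt)
  expect_equal(rep_$gdt_ha <= rep_$gdt_ts, TRUE)
  expect_gte(rep_$lga_s, min(rep_$gdt_ts, rep_$lcs))
  expect_lte(rep_$lga_s, max(rep_$gdt_ts, rep_$lcs))
  expect_equal(rep_$rmsd, superpose(mdl, tgt)$rmsd)
})
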