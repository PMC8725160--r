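# Synthetic diffraction laboratory: atomic models, direct-summation
# structure factors, Wilson normalization, and controlled target/model pair
# simulation at specified rmsd and fm.
#
# Scattering factors are constant f = atomic number (point-atom
# approximation): the likelihood theory operates on normalized amplitudes,
# where the resolution dependence of the form factor divides out shell by
# shell, and constant f keeps the independent test oracles exact.

.element_z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, SE = 34,
                MG = 12, FE = 26, ZN = 30, CA = 20, MN = 25, NA. = 11, K = 19)

#' Point-atom scattering factor (atomic number)
#'
#' @param element Character vector of element symbols.
#' @return Numeric scattering factors.
#' @export
scattering_factor <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA."
  z <- .element_z[key]
  if (any(is.na(z))) {
    stop_mrellg("unknown element(s): ", paste(unique(element[is.na(z)]), collapse = ", "))
  }
  unname(z)
}

#' Construct an atomic model
#'
#' @param atoms A data frame with columns `chain`, `resid` (integer residue
#'   number), `resname`, `atom` (atom name), `element`, `xf`, `yf`, `zf`
#'   (fractional coordinates), `occ` (occupancy in `[0, 1]`) and `b`
#'   (isotropic B factor in square angstroms, `>= 0`). An optional `delta`
#'   column carries a per-residue predicted coordinate error in angstroms.
#' @param cell The [unit_cell()] the fractional coordinates refer to.
#' @return An object of class `atomic_model` (the validated data frame with
#'   the cell as an attribute).
#' @export
atomic_model <- function(atoms, cell) {
  need <- c("chain", "resid", "resname", "atom", "element", "xf", "yf", "zf", "occ", "b")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop_mrellg("atoms lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop_mrellg("empty model")
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop_mrellg("occupancy must lie in [0, 1]")
  if (any(atoms$b < 0)) stop_mrellg("B factors must be >= 0")
  scattering_factor(atoms$element)  # validates elements
  structure(as.data.frame(atoms), class = c("atomic_model", "data.frame"), cell = cell)
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic model: %d atoms, %d residue(s)\n",
              nrow(x), length(unique(paste(x$chain, x$resid)))))
  invisible(x)
}

model_cell <- function(model) attr(model, "cell")

#' Total scattering power of a model
#'
#' `sum((occ * f)^2)` over atoms, with point-atom `f` (atomic number).
#'
#' @param model An `atomic_model` or `predicted_model`.
#' @return A single number.
#' @export
scattering_power <- function(model) {
  f <- scattering_factor(model$element)
  sum((model$occ * f)^2)
}

#' Structure factors by direct summation
#'
#' `F(h) = sum_j occ_j f_j exp(-B_j s^2 / 4) exp(2 pi i h . x_j)` with
#' `s = 1/d`.
#'
#' @param model An [atomic_model()].
#' @param reflections A `reflection_set` sharing the model's cell.
#' @return An `sf_set`: data frame with `h, k, l, d, centric, epsilon`,
#'   complex column `f` and amplitude column `amp`, carrying the cell as an
#'   attribute.
#' @export
calc_structure_factors <- function(model, reflections) {
  cellm <- model_cell(model)
  cellr <- attr(reflections, "cell")
  if (is.null(cellm) || is.null(cellr) || !cells_equal(cellm, cellr)) {
    stop_mrellg("model and reflections must share the same unit cell")
  }
  H <- as.matrix(reflections[, c("h", "k", "l")])
  storage.mode(H) <- "double"
  X <- as.matrix(model[, c("xf", "yf", "zf")])
  s2 <- 1 / reflections$d^2
  w <- model$occ * scattering_factor(model$element)
  phase <- 2 * pi * (H %*% t(X))                     # n_ref x n_atom
  damp <- exp(-outer(s2 / 4, model$b))               # n_ref x n_atom
  wre <- damp * cos(phase)
  wim <- damp * sin(phase)
  fre <- as.vector(wre %*% w)
  fim <- as.vector(wim %*% w)
  out <- data.frame(h = reflections$h, k = reflections$k, l = reflections$l,
                    d = reflections$d, centric = reflections$centric,
                    epsilon = reflections$epsilon)
  out$f <- complex(real = fre, imaginary = fim)
  out$amp <- Mod(out$f)
  structure(out, class = c("sf_set", "data.frame"), cell = cellm)
}

#' Assign reflections to resolution shells of equal count
#'
#' @param reflections A `reflection_set` or `sf_set`.
#' @param shells Number of shells, `>= 1`; each shell must receive at least
#'   one reflection.
#' @return Integer shell index per reflection (1 = lowest resolution).
#' @export
assign_shells <- function(reflections, shells) {
  n <- nrow(reflections)
  if (shells < 1) stop_mrellg("shells must be >= 1")
  if (n < shells) stop_mrellg("fewer reflections than shells: shell would be empty")
  # equal-count split in order of decreasing d
  rk <- rank(-reflections$d, ties.method = "first")
  as.integer(ceiling(rk * shells / n))
}

#' Wilson Sigma-N per resolution shell
#'
#' The random-atom (Wilson) expectation of the intensity:
#' `SigmaN(shell) = sum_j (occ_j f_j exp(-B_j s^2/4))^2` evaluated at the
#' shell's mean `s`.
#'
#' @param model An [atomic_model()].
#' @param reflections A `reflection_set`.
#' @param shells Number of equal-count resolution shells.
#' @return Data frame with one row per shell: `shell`, `n`, `s_mean`,
#'   `sigma_n`.
#' @export
wilson_sigma_n <- function(model, reflections, shells = 10L) {
  if (nrow(model) == 0) stop_mrellg("empty model")
  idx <- assign_shells(reflections, shells)
  s <- 1 / reflections$d
  f <- model$occ * scattering_factor(model$element)
  out <- lapply(sort(unique(idx)), function(sh) {
    sm <- mean(s[idx == sh])
    data.frame(shell = sh, n = sum(idx == sh), s_mean = sm,
               sigma_n = sum((f * exp(-model$b * sm^2 / 4))^2))
  })
  do.call(rbind, out)
}

#' Normalize structure-factor amplitudes to E values
#'
#' `E = |F| / sqrt(epsilon * scale_shell)`. In `"empirical"` mode the shell
#' scale is the shell mean of `|F|^2 / epsilon`, so the per-shell mean of the
#' epsilon-corrected `E^2` is exactly 1; in `"theoretical"` mode the scale is
#' the Wilson Sigma-N of a supplied model.
#'
#' @param sf An `sf_set` from [calc_structure_factors()], or any data frame
#'   with `d`, `epsilon` and `amp` columns.
#' @param shells Number of equal-count resolution shells.
#' @param mode `"empirical"` (default) or `"theoretical"`.
#' @param model Required in theoretical mode: the [atomic_model()] whose
#'   Sigma-N supplies the scale.
#' @return The input with a column `e` added and attribute `shell` (index per
#'   reflection).
#' @export
normalize_e <- function(sf, shells = 10L, mode = c("empirical", "theoretical"),
                        model = NULL) {
  mode <- match.arg(mode)
  if (!all(c("d", "epsilon", "amp") %in% names(sf))) {
    stop_mrellg("sf must carry d, epsilon and amp columns")
  }
  idx <- assign_shells(sf, shells)
  scale <- numeric(nrow(sf))
  if (mode == "empirical") {
    for (sh in sort(unique(idx))) {
      m <- mean(sf$amp[idx == sh]^2 / sf$epsilon[idx == sh])
      if (!is.finite(m) || m <= 0) stop_mrellg("degenerate shell ", sh, ": zero mean intensity")
      scale[idx == sh] <- m
    }
  } else {
    if (is.null(model)) stop_mrellg("theoretical mode requires a model")
    sn <- wilson_sigma_n(model, sf, shells)
    scale <- sn$sigma_n[match(idx, sn$shell)]
  }
  sf$e <- sf$amp / sqrt(sf$epsilon * scale)
  attr(sf, "shell") <- idx
  sf
}

# ---- Simulation -------------------------------------------------------------

random_model <- function(n_residues, cell, min_dist = 1.5) {
  n_atoms <- 4L * n_residues
  elements <- rep(c("N", "C", "C", "O"), n_residues)
  names_ <- rep(c("N", "CA", "C", "O"), n_residues)
  orth <- matrix(NA_real_, 0, 3)
  # uniform random fractional positions with a minimum-distance guard; the
  # guard keeps Wilson behaviour clean, clashes are otherwise irrelevant here
  tries <- 0L
  while (nrow(orth) < n_atoms) {
    cand_f <- matrix(stats::runif(3), 1, 3)
    cand <- frac_to_orth(cell, cand_f)
    if (nrow(orth) == 0 ||
        min(sqrt(rowSums((orth - matrix(cand, nrow(orth), 3, byrow = TRUE))^2))) >= min_dist) {
      orth <- rbind(orth, cand)
    }
    tries <- tries + 1L
    if (tries > 200L * n_atoms) stop_mrellg("cell too crowded for requested atom count")
  }
  frac <- orth_to_frac(cell, orth)
  atomic_model(data.frame(
    chain = "A", resid = rep(seq_len(n_residues), each = 4L),
    resname = "ALA", atom = names_, element = elements,
    xf = frac[, 1], yf = frac[, 2], zf = frac[, 3],
    occ = 1, b = 0, stringsAsFactors = FALSE
  ), cell)
}

#' Simulate a target/model structure pair at given rmsd and fm
#'
#' The target is a random structure (four point atoms per residue placed
#' uniformly in the cell with a 1.5-angstrom minimum-distance guard). The
#' model keeps a random subset of atoms whose scattering, `sum((occ f)^2)`,
#' is the requested fraction `fm` of the target total, then displaces each
#' retained atom by an isotropic Gaussian perturbation rescaled so that the
#' realized coordinate r.m.s.d. over retained atom pairs equals `rmsd`
#' exactly.
#'
#' @param n_residues Number of residues in the target.
#' @param cell A [unit_cell()].
#' @param rmsd Requested coordinate error in angstroms, `>= 0`.
#' @param fm Requested scattering fraction in `(0, 1]`.
#' @param seed Integer seed; identical seeds give identical pairs.
#' @return `list(target = <atomic_model>, model = <atomic_model>)`; the
#'   model carries attribute `target_index` giving, per model atom, the row
#'   of the corresponding target atom.
#' @export
simulate_pair <- function(n_residues, cell, rmsd, fm, seed) {
  if (!is.finite(fm) || fm <= 0 || fm > 1) stop_mrellg("fm must lie in (0, 1]")
  if (!is.finite(rmsd) || rmsd < 0) stop_mrellg("rmsd must be >= 0")
  with_seed(seed, {
    target <- random_model(n_residues, cell)
    f2 <- (target$occ * scattering_factor(target$element))^2
    total <- sum(f2)
    if (fm >= 1) {
      keep <- seq_len(nrow(target))
    } else {
      ord <- sample.int(nrow(target))
      cum <- cumsum(f2[ord])
      nkeep <- which(cum >= fm * total)[1]
      keep <- sort(ord[seq_len(nkeep)])
    }
    model <- target[keep, , drop = FALSE]
    orth <- frac_to_orth(cell, as.matrix(model[, c("xf", "yf", "zf")]))
    if (rmsd > 0) {
      disp <- matrix(stats::rnorm(3 * nrow(model)), ncol = 3)
      realized <- sqrt(mean(rowSums(disp^2)))
      orth <- orth + disp * (rmsd / realized)
    }
    frac <- orth_to_frac(cell, orth)
    model$xf <- frac[, 1]; model$yf <- frac[, 2]; model$zf <- frac[, 3]
    model <- atomic_model(model, cell)
    attr(model, "target_index") <- keep
    list(target = target, model = model)
  })
}

#' Simulate observed amplitudes from target structure factors
#'
#' Applies a seeded multiplicative Gaussian perturbation of relative standard
#' deviation `noise_fraction` to the target amplitudes, clipped at zero;
#' `noise_fraction = 0` returns the amplitudes exactly.
#'
#' @param target_sf An `sf_set` (or anything with an `amp` column).
#' @param noise_fraction Relative noise level, `>= 0`.
#' @param seed Integer seed.
#' @return Numeric vector of observed amplitudes.
#' @export
simulate_observed <- function(target_sf, noise_fraction = 0, seed = 1L) {
  if (!is.finite(noise_fraction) || noise_fraction < 0) {
    stop_mrellg("noise_fraction must be >= 0")
  }
  amp <- target_sf$amp
  if (noise_fraction == 0) return(amp)
  with_seed(seed, pmax(0, amp * (1 + noise_fraction * stats::rnorm(length(amp)))))
}
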