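# The sigma-A curve and the expected log-likelihood gain (eLLG).
#
# sigmaA is the resolution-dependent correlation between normalized model and
# target structure factors. For a model representing a scattering fraction fm
# whose coordinates carry Gaussian errors of r.m.s. magnitude `rmsd`,
#
#   sigmaA(d) = sqrt(fm) * (1 - fsol * exp(-bsol / (4 d^2)))
#                        * exp(-(2 pi^2 / 3) * rmsd^2 / d^2).
#
# The exponential factor is the Debye-Waller factor exp(-B s^2 / 4) for the
# B value equivalent to a positional error Delta, B = 8 pi^2 Delta^2 / 3,
# with s = 1/d; the Babinet-style solvent term (fsol, bsol) only matters at
# resolutions lower than about 8 A and defaults to off.
#
# The eLLG per reflection is the expectation of the per-reflection
# log-likelihood gain over the joint (E_obs, E_calc) distribution implied by
# sigmaA: Rice conditional for acentric reflections, Woolfson (folded-normal)
# for centric ones, against the Wilson baseline. That expectation has no
# elementary closed form (the small-signal limit is sigmaA^4/2 per acentric
# reflection); it is evaluated here by deterministic Gauss-Legendre
# quadrature, cached on a fine sigmaA grid for speed.

SIGMA_A_RMSD_CONST <- 2 * pi^2 / 3

#' Parameters of the sigma-A curve
#'
#' @param rmsd Effective coordinate error (VRMS) in angstroms, `>= 0`.
#' @param fm Fraction of the total scattering represented by the model, in
#'   `[0, 1]`.
#' @param fsol,bsol Babinet-style bulk-solvent parameters (amplitude fraction
#'   in `[0, 1]` and a B-like value in square angstroms, `>= 0`). Default
#'   `fsol = 0` disables the solvent term, which only affects resolutions
#'   lower than about 8 angstroms.
#' @return An object of class `sigmaa_params`.
#' @examples
#' p <- sigmaa_params(rmsd = 1.0, fm = 0.8)
#' sigma_a(p, d = 2.5)
#' @export
sigmaa_params <- function(rmsd, fm, fsol = 0, bsol = 0) {
  if (!is.finite(rmsd) || rmsd < 0) stop_mrellg("rmsd must be >= 0")
  if (!is.finite(fm) || fm < 0 || fm > 1) stop_mrellg("fm must lie in [0, 1]")
  if (!is.finite(fsol) || fsol < 0 || fsol > 1) stop_mrellg("fsol must lie in [0, 1]")
  if (!is.finite(bsol) || bsol < 0) stop_mrellg("bsol must be >= 0")
  structure(list(rmsd = rmsd, fm = fm, fsol = fsol, bsol = bsol),
            class = "sigmaa_params")
}

#' Evaluate the sigma-A curve
#'
#' @param params A [sigmaa_params()] object.
#' @param d Resolution(s) in angstroms; must be positive.
#' @return sigmaA value(s) in `[0, 1]`.
#' @export
sigma_a <- function(params, d) {
  if (!inherits(params, "sigmaa_params")) params <- do.call(sigmaa_params, params)
  if (any(!is.finite(d)) || any(d <= 0)) stop_mrellg("d must be positive")
  solv <- 1 - params$fsol * exp(-params$bsol / (4 * d^2))
  sqrt(params$fm) * solv * exp(-SIGMA_A_RMSD_CONST * params$rmsd^2 / d^2)
}

# ---- eLLG engine ------------------------------------------------------------

.mrellg_cache <- new.env(parent = emptyenv())

# Direct quadrature of E[LLG] at one sigmaA value.
# Outer integral over E_calc (Wilson marginal), inner over E_obs (conditional
# Rice / Woolfson), both with Gauss-Legendre rules; the inner window tracks
# the conditional's location and width so narrow high-sigmaA conditionals are
# resolved.
ellg_quadrature <- function(sa, centric, n_outer = 96L, n_inner = 96L) {
  if (sa == 0) return(0)
  base <- .mrellg_cache$gl_base
  if (is.null(base) || length(base$x) != n_outer) {
    base <- gauss_legendre(n_outer)
    .mrellg_cache$gl_base <- base
  }
  outer_hi <- if (centric) 5.8 else 5.2
  og <- gl_rescale(base, 0, outer_hi)
  sig <- if (centric) sqrt(1 - sa^2) else sqrt((1 - sa^2) / 2)
  total <- 0
  for (k in seq_len(n_outer)) {
    ec <- og$x[k]
    p_ec <- if (centric) sqrt(2 / pi) * exp(-ec^2 / 2) else 2 * ec * exp(-ec^2)
    lo <- max(0, sa * ec - 12 * sig)
    hi <- sa * ec + 12 * sig
    ig <- gl_rescale(base, lo, hi)
    eo <- ig$x
    if (centric) {
      x <- sa * eo * ec / (1 - sa^2)
      lc <- log_cosh(x)
      p_eo <- sqrt(2 / (pi * (1 - sa^2))) *
        exp(-(eo^2 + sa^2 * ec^2) / (2 * (1 - sa^2)) + lc)
      f <- lc - 0.5 * log(1 - sa^2) -
        (eo^2 + sa^2 * ec^2) / (2 * (1 - sa^2)) + eo^2 / 2
    } else {
      x <- 2 * sa * eo * ec / (1 - sa^2)
      li <- log_bessel_i0(x)
      p_eo <- 2 * eo / (1 - sa^2) *
        exp(-(eo^2 + sa^2 * ec^2) / (1 - sa^2) + li)
      f <- li - log(1 - sa^2) - (eo^2 + sa^2 * ec^2) / (1 - sa^2) + eo^2
    }
    total <- total + og$w[k] * p_ec * sum(ig$w * p_eo * f)
  }
  total
}

ELLG_GRID_MAX <- 0.9985

ellg_spline <- function(centric) {
  key <- if (centric) "spline_centric" else "spline_acentric"
  sp <- .mrellg_cache[[key]]
  if (is.null(sp)) {
    grid <- c(seq(0, 0.9, by = 0.004), seq(0.9025, ELLG_GRID_MAX, by = 0.002))
    vals <- vapply(grid, ellg_quadrature, numeric(1), centric = centric)
    sp <- stats::splinefun(grid, vals, method = "hyman")
    .mrellg_cache[[key]] <- sp
  }
  sp
}

ellg_sa <- function(sa, centric) {
  out <- numeric(length(sa))
  centric <- rep_len(centric, length(sa))
  for (flag in c(FALSE, TRUE)) {
    idx <- which(centric == flag & sa > 0 & sa < 1)
    if (!length(idx)) next
    v <- sa[idx]
    small <- v <= ELLG_GRID_MAX
    if (any(small)) out[idx[small]] <- ellg_spline(flag)(v[small])
    if (any(!small)) {
      out[idx[!small]] <- vapply(v[!small], ellg_quadrature, numeric(1), centric = flag)
    }
  }
  if (any(sa >= 1)) {
    warning("sigmaA = 1: eLLG diverges for a perfect complete model; returning +Inf")
    out[sa >= 1] <- Inf
  }
  out
}

#' Expected log-likelihood gain of one reflection
#'
#' The expectation of the per-reflection amplitude LLG (Rice form for
#' acentric reflections, Woolfson form for centric ones, relative to the
#' Wilson baseline) over the joint distribution of observed and calculated
#' normalized amplitudes at correlation `sigma_a`. Evaluated by
#' deterministic quadrature; `0` at `sigma_a = 0`, strictly increasing, and
#' approximately `sigma_a^4 / 2` for small values. At `sigma_a = 1` the eLLG
#' diverges and `+Inf` is returned with a warning.
#'
#' @param sigma_a sigmaA value(s) in `[0, 1]`.
#' @param centric Logical flag(s), recycled along `sigma_a`.
#' @return Nonnegative eLLG value(s), in log units.
#' @export
ellg_per_reflection <- function(sigma_a, centric = FALSE) {
  if (any(!is.finite(sigma_a)) || any(sigma_a < 0) || any(sigma_a > 1)) {
    stop_mrellg("sigma_a must lie in [0, 1]")
  }
  ellg_sa(sigma_a, centric)
}

#' Total eLLG of a model over a reflection set
#'
#' Sums [ellg_per_reflection()] over all reflections, each evaluated at the
#' sigmaA given by the four-parameter curve at that reflection's resolution
#' and with its centric flag.
#'
#' @param params A [sigmaa_params()] object.
#' @param reflections A `reflection_set` from [generate_reflections()].
#' @return The total eLLG (nonnegative, log units).
#' @export
total_ellg <- function(params, reflections) {
  if (!inherits(reflections, "reflection_set") || nrow(reflections) == 0) {
    stop_mrellg("reflections must be a non-empty reflection_set")
  }
  sa <- sigma_a(params, reflections$d)
  sum(ellg_sa(sa, reflections$centric))
}

#' Coordinate error required to reach a target eLLG
#'
#' Inverts the monotone map rmsd -> total eLLG at fixed `fm` by bisection on
#' `rmsd` in `[0, 10]` angstroms (extended upward if needed). When even a
#' perfect-coordinate model (`rmsd = 0`) cannot reach the target, there is no
#' solution and `NA` is returned with a warning rather than silently
#' clamping.
#'
#' @param fm Scattering fraction of the model, in `(0, 1]`.
#' @param reflections A `reflection_set`.
#' @param target_ellg Positive target total eLLG.
#' @param fsol,bsol Optional solvent parameters passed to [sigmaa_params()].
#' @param tol Relative tolerance on the achieved total eLLG.
#' @return Required rmsd in angstroms, or `NA_real_` when unreachable.
#' @export
solve_required_rmsd <- function(fm, reflections, target_ellg,
                                fsol = 0, bsol = 0, tol = 1e-8) {
  if (!is.finite(target_ellg) || target_ellg <= 0) stop_mrellg("target_ellg must be positive")
  f <- function(r) total_ellg(sigmaa_params(r, fm, fsol, bsol), reflections)
  top <- f(0)
  if (top < target_ellg) {
    warning(sprintf(
      "target eLLG %.6g unreachable: even rmsd = 0 gives only %.6g", target_ellg, top))
    return(NA_real_)
  }
  if (abs(top - target_ellg) <= tol * target_ellg) return(0)
  hi <- 10
  while (f(hi) > target_ellg && hi < 80) hi <- hi * 2
  root <- stats::uniroot(function(r) f(r) - target_ellg, c(0, hi),
                         tol = 1e-12)$root
  root
}

#' Grid of total eLLG values over rmsd and fm axes
#'
#' Entry `(i, j)` is the total eLLG at `rmsd_values[i]`, `fm_values[j]`; the
#' grid underlies contour plots of phasing feasibility.
#'
#' @param rmsd_values,fm_values Non-empty numeric axes.
#' @param reflections A `reflection_set`.
#' @param fsol,bsol Optional solvent parameters.
#' @return A numeric matrix with rmsd along rows and fm along columns,
#'   with the axes as dimnames.
#' @export
ellg_grid <- function(rmsd_values, fm_values, reflections, fsol = 0, bsol = 0) {
  if (!length(rmsd_values) || !length(fm_values)) stop_mrellg("empty grid axes")
  out <- matrix(NA_real_, length(rmsd_values), length(fm_values),
                dimnames = list(signif(rmsd_values, 6), signif(fm_values, 6)))
  for (j in seq_along(fm_values)) {
    for (i in seq_along(rmsd_values)) {
      out[i, j] <- total_ellg(sigmaa_params(rmsd_values[i], fm_values[j], fsol, bsol),
                              reflections)
    }
  }
  out
}
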