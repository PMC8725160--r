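# Rice/Woolfson amplitude log-likelihood gain against the Wilson baseline,
# the Monte-Carlo eLLG oracle, VRMS refinement by LLG maximization, and
# pose-significance classification.
#
# The likelihood is the probability of the observed normalized amplitude
# given the calculated one and sigmaA; the LLG subtracts the log-likelihood
# of the Wilson (random-atom) baseline. On normalized amplitudes E the
# baseline is Rayleigh (acentric) or half-normal (centric) and the
# conditional is Rice or Woolfson respectively. Epsilon factors are divided
# into the normalization before these forms apply.

llg_contrib <- function(e_obs, e_calc, sa, centric) {
  out <- numeric(length(e_obs))
  ac <- !centric & sa > 0 & sa < 1
  if (any(ac)) {
    v <- 1 - sa[ac]^2
    x <- 2 * sa[ac] * e_obs[ac] * e_calc[ac] / v
    out[ac] <- log_bessel_i0(x) - log(v) -
      (e_obs[ac]^2 + sa[ac]^2 * e_calc[ac]^2) / v + e_obs[ac]^2
  }
  ce <- centric & sa > 0 & sa < 1
  if (any(ce)) {
    v <- 1 - sa[ce]^2
    x <- sa[ce] * e_obs[ce] * e_calc[ce] / v
    out[ce] <- log_cosh(x) - 0.5 * log(v) -
      (e_obs[ce]^2 + sa[ce]^2 * e_calc[ce]^2) / (2 * v) + e_obs[ce]^2 / 2
  }
  if (any(sa >= 1)) {
    lim <- sa >= 1
    out[lim] <- ifelse(abs(e_obs[lim] - e_calc[lim]) < 1e-12, Inf, -Inf)
  }
  out  # sa == 0 contributes exactly 0
}

#' Amplitude log-likelihood gain of a model
#'
#' Per-reflection LLG contributions `log p(E_obs | E_calc, sigmaA) -
#' log p_Wilson(E_obs)`: Rice form for acentric reflections, Woolfson form
#' for centric ones. At `sigmaA = 0` a reflection contributes exactly 0; at
#' `sigmaA = 1` it contributes `-Inf` unless `E_obs = E_calc`.
#'
#' @param e_obs,e_calc Observed and calculated normalized amplitudes
#'   (epsilon-corrected E values), aligned vectors.
#' @param sigma_a Per-reflection sigmaA values in `[0, 1]` (recycled if
#'   scalar).
#' @param centric Per-reflection centric flags (recycled if scalar).
#' @return An object of class `llg_result`: `list(total, contributions,
#'   sigma_a, vrms)` with `total = sum(contributions)`.
#' @export
llg <- function(e_obs, e_calc, sigma_a, centric = FALSE) {
  n <- length(e_obs)
  if (length(e_calc) != n) stop_mrellg("e_obs and e_calc lengths differ")
  sigma_a <- rep_len(sigma_a, n)
  centric <- rep_len(centric, n)
  if (any(sigma_a < 0) || any(sigma_a > 1)) stop_mrellg("sigma_a must lie in [0, 1]")
  contrib <- llg_contrib(e_obs, e_calc, sigma_a, centric)
  structure(list(total = sum(contrib), contributions = contrib,
                 sigma_a = sigma_a, vrms = NA_real_),
            class = "llg_result")
}

#' @export
print.llg_result <- function(x, ...) {
  cat(sprintf("LLG total = %.3f over %d reflections", x$total, length(x$contributions)))
  if (!is.na(x$vrms)) cat(sprintf("  (refined VRMS = %.3f A)", x$vrms))
  cat("\n")
  invisible(x)
}

#' Monte-Carlo expected LLG per reflection
#'
#' Draws `(E_obs, E_calc)` pairs from the joint sigmaA model (Wilson marginal
#' for `E_calc`, Rice/Woolfson conditional for `E_obs`) and averages the
#' per-reflection LLG. This is the sampling route to the same expectation
#' that [ellg_per_reflection()] computes by quadrature, and serves as its
#' independent oracle.
#'
#' @param sigma_a A single sigmaA value in `[0, 1)`.
#' @param centric Single logical flag.
#' @param n_sims Number of draws, `>= 2`.
#' @param seed Integer seed.
#' @return `list(mean, se, n)` with the standard error of the mean.
#' @export
expected_llg_mc <- function(sigma_a, centric = FALSE, n_sims = 1000L, seed = 1L) {
  if (length(sigma_a) != 1 || sigma_a < 0 || sigma_a >= 1) {
    stop_mrellg("sigma_a must be a single value in [0, 1)")
  }
  if (n_sims < 2) stop_mrellg("n_sims must be >= 2")
  with_seed(seed, {
    if (centric) {
      e_calc <- abs(stats::rnorm(n_sims))
      e_obs <- abs(sigma_a * e_calc + sqrt(1 - sigma_a^2) * stats::rnorm(n_sims))
    } else {
      e_calc <- sqrt(stats::rexp(n_sims))   # Rayleigh with E[E^2] = 1
      sd2 <- sqrt((1 - sigma_a^2) / 2)
      re <- sigma_a * e_calc + stats::rnorm(n_sims, sd = sd2)
      im <- stats::rnorm(n_sims, sd = sd2)
      e_obs <- sqrt(re^2 + im^2)
    }
    v <- llg_contrib(e_obs, e_calc, rep(sigma_a, n_sims), rep(centric, n_sims))
    list(mean = mean(v), se = stats::sd(v) / sqrt(n_sims), n = n_sims)
  })
}

#' Refine the effective coordinate error (VRMS) by LLG maximization
#'
#' Maximizes the total LLG over the model r.m.s.d. entering the sigmaA curve
#' at fixed `fm`, by bounded golden-section/Brent search on
#' `[0.01, 5]` angstroms. The initial value defaults to 1.2 angstroms, the
#' standard starting VRMS for posed predicted models; the returned optimum
#' never scores below it.
#'
#' @param e_obs,e_calc Aligned normalized amplitude vectors.
#' @param fm Scattering fraction of the model, in `(0, 1]`.
#' @param reflections The `reflection_set` the amplitudes are aligned with
#'   (supplies `d` and centric flags).
#' @param init Initial VRMS in angstroms (default 1.2).
#' @param interval Search bounds in angstroms.
#' @return An `llg_result` whose `vrms` field holds the refined value.
#' @export
refine_vrms <- function(e_obs, e_calc, fm, reflections, init = 1.2,
                        interval = c(0.01, 5)) {
  if (!is.finite(init) || init <= 0) stop_mrellg("init must be positive")
  if (nrow(reflections) != length(e_obs)) {
    stop_mrellg("reflections and amplitude vectors are misaligned")
  }
  obj <- function(r) {
    sa <- sigma_a(sigmaa_params(r, fm), reflections$d)
    sum(llg_contrib(e_obs, e_calc, sa, reflections$centric))
  }
  opt <- stats::optimize(obj, interval = interval, maximum = TRUE, tol = 1e-6)
  cand <- c(opt$maximum, init, interval)
  vals <- vapply(cand, obj, numeric(1))
  if (all(!is.finite(vals))) stop_mrellg("VRMS refinement failed: non-finite LLG everywhere")
  best <- cand[which.max(vals)]
  sa <- sigma_a(sigmaa_params(best, fm), reflections$d)
  res <- llg(e_obs, e_calc, sa, reflections$centric)
  res$vrms <- best
  res
}

.pose_thresholds <- c(nonpolar = 60, polar = 50, P1 = 30)

#' Pose-significance threshold for a space-group class
#'
#' @param space_group_class One of `"nonpolar"`, `"polar"`, `"P1"`.
#' @return The LLG threshold (60, 50 or 30 respectively).
#' @export
pose_llg_threshold <- function(space_group_class) {
  space_group_class <- match.arg(space_group_class, names(.pose_thresholds))
  unname(.pose_thresholds[space_group_class])
}

#' Classify a pose as probably correct from its LLG
#'
#' A pose is probably correct when its LLG strictly exceeds a
#' space-group-class-dependent threshold: 60 in nonpolar space groups, 50 in
#' polar space groups, 30 in P1.
#'
#' @param llg_total Total LLG of the pose.
#' @param space_group_class One of `"nonpolar"`, `"polar"`, `"P1"`.
#' @return `TRUE` if the pose is probably correct.
#' @export
classify_pose <- function(llg_total, space_group_class) {
  if (!is.finite(llg_total)) stop_mrellg("llg_total must be finite")
  llg_total > pose_llg_threshold(space_group_class)
}

#' LLG with per-atom error weighting versus a uniform B factor
#'
#' Computes the model LLG twice against amplitudes derived from the target:
#' once with each atom's B factor set from its recorded per-residue
#' coordinate-error estimate via `B = 8 pi^2 Delta^2 / 3`, and once with a
#' single uniform B (the scattering-weighted mean of the converted values by
#' default). Accurate heterogeneous error estimates increase the LLG; for a
#' homogeneous-error model the two agree.
#'
#' In both runs the effective r.m.s.d. entering sigmaA is refined by
#' [refine_vrms()], so the comparison isolates the benefit of the per-atom
#' weighting itself.
#'
#' @param target An [atomic_model()]: the true structure.
#' @param model An [atomic_model()] carrying a `delta` column (per-residue
#'   predicted coordinate error in angstroms).
#' @param reflections A `reflection_set` on the shared cell.
#' @param shells Resolution shells for normalization.
#' @param uniform_b Optional uniform B override in square angstroms.
#' @return `list(weighted = <llg_result>, uniform = <llg_result>, fm)`.
#' @export
weighting_benefit <- function(target, model, reflections, shells = 10L,
                              uniform_b = NULL) {
  if (is.null(model$delta) || any(is.na(model$delta))) {
    stop_mrellg("model must carry a complete per-residue 'delta' column")
  }
  cell <- model_cell(model)
  e_obs <- normalize_e(calc_structure_factors(target, reflections), shells)$e
  fm <- min(1, scattering_power(model) / scattering_power(target))
  run <- function(bvals) {
    m <- model
    m$b <- bvals
    e_calc <- normalize_e(calc_structure_factors(m, reflections), shells)$e
    refine_vrms(e_obs, e_calc, fm, reflections)
  }
  b_weighted <- error_to_bfactor(model$delta)
  w <- (model$occ * scattering_factor(model$element))^2
  b_uni <- uniform_b %||% sum(w * b_weighted) / sum(w)
  list(weighted = run(b_weighted), uniform = run(rep(b_uni, nrow(model))), fm = fm)
}
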