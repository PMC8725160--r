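# Model-vs-target structural scores: least-squares superposition and
# r.m.s.d., GDT_TS/GDT_HA, LCS, an LGA_S-style combination, and
# helix-geometry analysis (bending and inter-axis angles).
#
# Pairing is sequence-dependent (1:1 by residue index). The GDT
# superposition search is an iterative seed-and-extend procedure (seed
# windows, superpose, count inliers, re-superpose on inliers), a documented
# simplification of the full LGA search.

as_coords <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) != 3) stop_mrellg("coordinates must be an n x 3 matrix")
  storage.mode(m) <- "double"
  m
}

#' Least-squares superposition of two paired coordinate sets
#'
#' Kabsch algorithm: the proper rotation and translation minimizing the
#' r.m.s.d. of `a` onto `b` over the given pairing.
#'
#' @param a,b `n x 3` coordinate matrices (e.g. CA atoms).
#' @param pairing Optional two-column index matrix (rows of `a` paired with
#'   rows of `b`); defaults to row-by-row pairing.
#' @return An object of class `superposition`: `list(rotation, translation,
#'   rmsd, n)`. Row vectors transform as `x %*% rotation + translation`.
#' @export
superpose <- function(a, b, pairing = NULL) {
  a <- as_coords(a); b <- as_coords(b)
  if (!is.null(pairing)) {
    pairing <- rbind(pairing)
    a <- a[pairing[, 1], , drop = FALSE]
    b <- b[pairing[, 2], , drop = FALSE]
  }
  n <- nrow(a)
  if (nrow(b) != n) stop_mrellg("paired coordinate sets differ in length")
  if (n < 3) stop_mrellg("need at least 3 pairs for a superposition")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  sv_a <- svd(a0)$d
  if (sv_a[2] < 1e-9 * max(sv_a[1], 1)) {
    stop_mrellg("degenerate (collinear) geometry: superposition undetermined")
  }
  C <- crossprod(a0, b0)
  sv <- svd(C)
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  e0 <- sum(a0^2) + sum(b0^2)
  msd <- max(0, (e0 - 2 * (sv$d[1] + sv$d[2] + d * sv$d[3])) / n)
  structure(list(rotation = R, translation = cb - as.vector(ca %*% R),
                 rmsd = sqrt(msd), n = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition over %d pairs: rmsd = %.4f A\n", x$n, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sp A [superpose()] result.
#' @param coords An `n x 3` matrix.
#' @return The transformed `n x 3` matrix.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(as_coords(coords) %*% sp$rotation, 2, -sp$translation)
}

#' Global distance test (GDT) score
#'
#' For each distance cutoff, the maximal percentage of CA pairs that can be
#' brought within the cutoff over the searched superpositions; the score is
#' the mean over cutoffs. With a user-supplied fixed superposition the score
#' reduces to simple distance counting under that superposition.
#'
#' The search builds a shared pool of candidate superpositions (seed windows
#' of 3/5/7 residues plus the global fit, each refined by re-superposing on
#' its inliers), and evaluates every candidate against every cutoff, so a
#' larger cutoff never scores below a smaller one.
#'
#' @param coords_model,coords_target Paired `n x 3` CA coordinate matrices.
#' @param cutoffs Distance cutoffs in angstroms; `c(1, 2, 4, 8)` gives
#'   GDT_TS, `c(0.5, 1, 2, 4)` gives GDT_HA.
#' @param superposition Optional fixed [superpose()] object (or `"identity"`
#'   to compare coordinates as given).
#' @param seed_lengths Seed window lengths for the search.
#' @param max_iter Inlier re-superposition rounds per seed and cutoff.
#' @return The GDT score as a percentage in `[0, 100]`, with attribute
#'   `per_cutoff` (best fraction per cutoff).
#' @export
gdt <- function(coords_model, coords_target, cutoffs = c(1, 2, 4, 8),
                superposition = NULL, seed_lengths = c(3, 5, 7), max_iter = 4L) {
  a <- as_coords(coords_model); b <- as_coords(coords_target)
  n <- nrow(a)
  if (n == 0 || nrow(b) != n) stop_mrellg("need non-empty paired coordinate sets")
  dist_under <- function(x) sqrt(rowSums((x - b)^2))
  if (!is.null(superposition)) {
    dd <- if (identical(superposition, "identity")) dist_under(a)
          else dist_under(apply_superposition(superposition, a))
    frac <- vapply(cutoffs, function(cc) mean(dd <= cc), numeric(1))
    return(structure(100 * mean(frac),
                     per_cutoff = stats::setNames(frac, cutoffs)))
  }
  best <- rep(0, length(cutoffs))
  consider <- function(dd) best <<- pmax(best, vapply(cutoffs, function(cc) mean(dd <= cc), numeric(1)))
  candidates <- list()
  if (n >= 3) candidates[[1]] <- superpose(a, b)
  for (w in seed_lengths[seed_lengths <= n]) {
    for (s in seq_len(n - w + 1L)) {
      idx <- s:(s + w - 1L)
      sp <- tryCatch(superpose(a[idx, , drop = FALSE], b[idx, , drop = FALSE]),
                     error = function(e) NULL)
      if (!is.null(sp)) candidates[[length(candidates) + 1L]] <- sp
    }
  }
  for (sp in candidates) {
    dd <- dist_under(apply_superposition(sp, a))
    consider(dd)
    for (cc in cutoffs) {
      d_it <- dd
      for (it in seq_len(max_iter)) {
        inl <- which(d_it <= cc)
        if (length(inl) < 3) break
        sp2 <- tryCatch(superpose(a[inl, , drop = FALSE], b[inl, , drop = FALSE]),
                        error = function(e) NULL)
        if (is.null(sp2)) break
        d_new <- dist_under(apply_superposition(sp2, a))
        consider(d_new)
        if (identical(which(d_new <= cc), inl)) break
        d_it <- d_new
      }
    }
  }
  structure(100 * mean(best), per_cutoff = stats::setNames(best, cutoffs))
}

#' @rdname gdt
#' @param ... Passed on to [gdt()].
#' @export
gdt_ts <- function(coords_model, coords_target, ...) {
  gdt(coords_model, coords_target, cutoffs = c(1, 2, 4, 8), ...)
}

#' @rdname gdt
#' @export
gdt_ha <- function(coords_model, coords_target, ...) {
  gdt(coords_model, coords_target, cutoffs = c(0.5, 1, 2, 4), ...)
}

# Minimized rmsd of a contiguous window from precomputed prefix sums.
window_rmsd <- function(pre, i, j) {
  w <- j - i + 1
  sa <- pre$sa[j + 1, ] - pre$sa[i, ]
  sb <- pre$sb[j + 1, ] - pre$sb[i, ]
  C <- matrix(pre$sab[j + 1, ] - pre$sab[i, ], 3, 3) - tcrossprod(sa, sb) / w
  e0 <- (pre$qa[j + 1] - pre$qa[i]) - sum(sa^2) / w +
        (pre$qb[j + 1] - pre$qb[i]) - sum(sb^2) / w
  sv <- svd(C)
  d <- sign(det(sv$u) * det(sv$v))
  sqrt(max(0, (e0 - 2 * (sv$d[1] + sv$d[2] + d * sv$d[3])) / w))
}

#' Longest continuous segment (LCS) under an r.m.s.d. cutoff
#'
#' The longest contiguous residue window whose own least-squares
#' superposition has r.m.s.d. at most the cutoff, as a percentage of the
#' full chain length. Windows shorter than 3 residues are not considered.
#'
#' @param coords_model,coords_target Paired, residue-ordered `n x 3` CA
#'   coordinate matrices.
#' @param rmsd_cutoff Cutoff in angstroms.
#' @return Percentage in `[0, 100]`, with attribute `window` (start and end
#'   indices of the best segment, or `NULL` if none of length >= 3 fits).
#' @export
lcs <- function(coords_model, coords_target, rmsd_cutoff = 4) {
  a <- as_coords(coords_model); b <- as_coords(coords_target)
  n <- nrow(a)
  if (n == 0 || nrow(b) != n) stop_mrellg("need non-empty paired coordinate sets")
  if (n < 3) stop_mrellg("chain too short for LCS (need >= 3 residues)")
  cross <- t(vapply(seq_len(n), function(i) as.vector(tcrossprod(a[i, ], b[i, ])), numeric(9)))
  pre <- list(
    sa = rbind(0, apply(a, 2, cumsum)),
    sb = rbind(0, apply(b, 2, cumsum)),
    sab = rbind(0, apply(cross, 2, cumsum)),
    qa = c(0, cumsum(rowSums(a^2))),
    qb = c(0, cumsum(rowSums(b^2)))
  )
  for (len in n:3) {
    for (s in seq_len(n - len + 1L)) {
      if (window_rmsd(pre, s, s + len - 1L) <= rmsd_cutoff) {
        return(structure(100 * len / n, window = c(s, s + len - 1L)))
      }
    }
  }
  structure(0, window = NULL)
}

#' LGA_S-style combination of GDT and LCS scores
#'
#' A weighted average `weight * GDT + (1 - weight) * LCS`. The exact
#' combination used inside LGA is not published here; the default weight of
#' 0.75 toward GDT is a documented approximation.
#'
#' @param gdt_score,lcs_score Percentages in `[0, 100]`.
#' @param weight Weight on the GDT term, in `[0, 1]`.
#' @return A percentage in `[0, 100]`.
#' @export
lga_s <- function(gdt_score, lcs_score, weight = 0.75) {
  if (any(c(gdt_score, lcs_score) < 0) || any(c(gdt_score, lcs_score) > 100)) {
    stop_mrellg("scores must lie in [0, 100]")
  }
  if (weight < 0 || weight > 1) stop_mrellg("weight must lie in [0, 1]")
  weight * gdt_score + (1 - weight) * lcs_score
}

# ---- Helix geometry ---------------------------------------------------------

unit_vec <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop_mrellg("zero-length vector")
  v / nv
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

#' Local helix axes and bending analysis
#'
#' Local axis directions are computed for every window of four consecutive
#' CA atoms by the Sugeta-Miyazawa construction (the cross product of
#' successive bond-vector differences points along the local helix axis).
#' The bending angle is the angle between local axes one helical turn apart;
#' the helix is classified from the maximum bending angle: `kinked` at or
#' above `kink_threshold`, `linear` below `linear_threshold`, otherwise
#' `curved`.
#'
#' @param ca `n x 3` matrix of CA coordinates of one helix, `n >= 6`.
#' @param turn_offset Separation (in residues) between compared local axes;
#'   4 approximates one turn. Reduced automatically for short helices.
#' @param kink_threshold,linear_threshold Class boundaries in degrees
#'   (defaults 20 and 5).
#' @return `list(local_axes, bending_angles, avg_bend, max_bend, class,
#'   axis)` where `axis` is the overall least-squares helix axis (first
#'   principal component of the CA set, oriented along the chain) and angles
#'   are in degrees.
#' @export
helix_axes <- function(ca, turn_offset = 4L, kink_threshold = 20,
                       linear_threshold = 5) {
  ca <- as_coords(ca)
  n <- nrow(ca)
  if (n < 6) stop_mrellg("helix too short: need >= 6 CA atoms")
  n_ax <- n - 3L
  axes <- matrix(NA_real_, n_ax, 3)
  for (i in seq_len(n_ax)) {
    v1 <- ca[i + 1, ] - ca[i, ]
    v2 <- ca[i + 2, ] - ca[i + 1, ]
    v3 <- ca[i + 3, ] - ca[i + 2, ]
    ax <- cross3(v1 - v2, v2 - v3)
    ax <- unit_vec(ax)
    if (sum(ax * (ca[i + 3, ] - ca[i, ])) < 0) ax <- -ax
    axes[i, ] <- ax
  }
  off <- min(as.integer(turn_offset), n_ax - 1L)
  if (off < 1L) stop_mrellg("helix too short for bending analysis")
  bend <- vapply(seq_len(n_ax - off), function(i) {
    ang <- sum(axes[i, ] * axes[i + off, ])
    acos(max(-1, min(1, ang))) * 180 / pi
  }, numeric(1))
  cls <- if (max(bend) >= kink_threshold) "kinked"
         else if (max(bend) < linear_threshold) "linear"
         else "curved"
  pc <- svd(sweep(ca, 2, colMeans(ca)))$v[, 1]
  if (sum(pc * (ca[n, ] - ca[1, ])) < 0) pc <- -pc
  list(local_axes = axes, bending_angles = bend,
       avg_bend = mean(bend), max_bend = max(bend), class = cls, axis = pc)
}

#' Angle between two helix axes
#'
#' @param axis_1,axis_2 Non-zero 3-vectors (e.g. the `axis` field of
#'   [helix_axes()]).
#' @param mode `"unsigned"` returns the angle in `[0, 180]` degrees;
#'   `"signed"` additionally takes its sign from the orientation of the two
#'   axes around a reference direction (the sign of
#'   `det[axis_1, axis_2, reference]`). The signed convention is exposed
#'   because published inter-helix angles use varying conventions.
#' @param reference Reference 3-vector required in signed mode (e.g. the
#'   centroid-to-centroid vector between the helices).
#' @return Angle in degrees.
#' @export
inter_helix_angle <- function(axis_1, axis_2, mode = c("unsigned", "signed"),
                              reference = NULL) {
  mode <- match.arg(mode)
  u <- unit_vec(as.numeric(axis_1))
  v <- unit_vec(as.numeric(axis_2))
  ang <- acos(max(-1, min(1, sum(u * v)))) * 180 / pi
  if (mode == "signed") {
    if (is.null(reference)) stop_mrellg("signed mode needs a reference vector")
    s <- det(cbind(u, v, unit_vec(as.numeric(reference))))
    if (s < 0) ang <- -ang
  }
  ang
}

#' Score a model against a target
#'
#' Convenience wrapper producing the full score report: superposition
#' r.m.s.d., GDT_TS, GDT_HA, LCS and the LGA_S-style combination.
#'
#' @param coords_model,coords_target Paired `n x 3` CA coordinate matrices.
#' @param lcs_cutoff LCS r.m.s.d. cutoff in angstroms.
#' @param lga_weight Weight on GDT inside the LGA_S-style combination.
#' @return A one-row data frame with columns `rmsd`, `gdt_ts`, `gdt_ha`,
#'   `lcs`, `lga_s`.
#' @export
score_report <- function(coords_model, coords_target, lcs_cutoff = 4,
                         lga_weight = 0.75) {
  sp <- superpose(coords_model, coords_target)
  g_ts <- gdt_ts(coords_model, coords_target)
  g_ha <- gdt_ha(coords_model, coords_target)
  l <- lcs(coords_model, coords_target, lcs_cutoff)
  data.frame(rmsd = sp$rmsd, gdt_ts = as.numeric(g_ts), gdt_ha = as.numeric(g_ha),
             lcs = as.numeric(l), lga_s = lga_s(as.numeric(g_ts), as.numeric(l), lga_weight))
}
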