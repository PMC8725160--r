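# Unit-cell geometry, symmetry operators, and reflection generation.
#
# Everything downstream (structure factors, Wilson statistics, eLLG totals)
# sums over a set of Friedel-unique reflections with d-spacings, centric
# flags and epsilon multiplicity factors; this file provides that plumbing.
# Coordinates are fractional internally; orthogonal angstroms appear only at
# I/O boundaries.

#' Construct a unit cell
#'
#' @param a,b,c Cell edge lengths in angstroms; all must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#'
#' @return An object of class `unit_cell` carrying the cell constants, the
#'   orthogonalization matrix (fractional -> orthogonal angstroms, PDB
#'   convention with `a` along x), the direct and reciprocal metric tensors
#'   and the cell volume.
#'
#' @examples
#' cell <- unit_cell(10, 10, 10)
#' d_spacing(cell, c(1, 0, 0))
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a, b, c)
  ang <- c(alpha, beta, gamma)
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop_mrellg("cell lengths must be positive and finite")
  }
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180)) {
    stop_mrellg("cell angles must lie in (0, 180) degrees")
  }
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  vfac <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vfac <= 0) stop_mrellg("degenerate cell: metric tensor not positive definite")
  # Orthogonalization matrix, a along x, b in the xy plane.
  ortho <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0, c * sqrt(vfac) / sg
  ), nrow = 3, byrow = TRUE)
  metric <- crossprod(ortho)           # direct metric tensor G
  recip <- solve(metric)               # reciprocal metric tensor G*
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         ortho = ortho, metric = metric, recip_metric = recip,
         volume = a * b * c * sqrt(vfac)),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

cells_equal <- function(c1, c2, tol = 1e-6) {
  all(abs(unlist(c1[c("a", "b", "c", "alpha", "beta", "gamma")]) -
            unlist(c2[c("a", "b", "c", "alpha", "beta", "gamma")])) < tol)
}

#' Convert fractional coordinates to orthogonal angstroms (and back)
#'
#' @param cell A [unit_cell()].
#' @param xyz An `n x 3` matrix of coordinates.
#' @return An `n x 3` matrix in the other frame.
#' @export
frac_to_orth <- function(cell, xyz) {
  xyz <- rbind(xyz)[, 1:3, drop = FALSE]
  t(cell$ortho %*% t(xyz))
}

#' @rdname frac_to_orth
#' @export
orth_to_frac <- function(cell, xyz) {
  xyz <- rbind(xyz)[, 1:3, drop = FALSE]
  t(solve(cell$ortho) %*% t(xyz))
}

#' Resolution (d-spacing) of a reflection
#'
#' `d = 1 / |h . a* + k . b* + l . c*|`, evaluated through the reciprocal
#' metric tensor.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer triple, or an `n x 3` matrix of triples.
#' @return d-spacing(s) in angstroms.
#' @export
d_spacing <- function(cell, hkl) {
  h <- rbind(hkl)
  storage.mode(h) <- "double"
  if (ncol(h) != 3) stop_mrellg("hkl must have three columns")
  if (any(rowSums(h != 0) == 0)) stop_mrellg("invalid reflection (0,0,0)")
  inv_d2 <- rowSums((h %*% cell$recip_metric) * h)
  unname(1 / sqrt(inv_d2))
}

# ---- Symmetry operators -----------------------------------------------------

parse_one_symop <- function(txt) {
  parts <- strsplit(gsub("[[:space:]]", "", txt), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop_mrellg("symmetry operator must have three components: ", txt)
  env0 <- function(x, y, z) {
    lapply(parts, function(p) {
      ex <- tryCatch(parse(text = p)[[1]], error = function(e) {
        stop_mrellg("cannot parse symmetry operator component: ", p)
      })
      eval(ex, list(x = x, y = y, z = z))
    })
  }
  t0 <- unlist(env0(0, 0, 0))
  R <- cbind(unlist(env0(1, 0, 0)) - t0,
             unlist(env0(0, 1, 0)) - t0,
             unlist(env0(0, 0, 1)) - t0)
  if (max(abs(R - round(R))) > 1e-9) stop_mrellg("non-integer rotation part in: ", txt)
  R <- round(R)
  if (abs(abs(det(R)) - 1) > 1e-9) stop_mrellg("rotation part must have determinant +-1: ", txt)
  list(R = R, t = t0 %% 1)
}

#' Symmetry operators from "x,y,z"-style triplet strings
#'
#' Space-group symmetry is supplied as an explicit operator list (the package
#' needs only centricity and epsilon factors, not full space-group machinery).
#' A small built-in table covers common groups; see [space_group_ops()].
#'
#' @param triplets Character vector such as `c("x,y,z", "-x,y+1/2,-z")`.
#' @return An object of class `symops`: a list of `list(R = <3x3 integer
#'   matrix>, t = <fractional translation>)` pairs, identity included.
#' @export
symops <- function(triplets) {
  if (length(triplets) == 0) stop_mrellg("empty symmetry operator list")
  ops <- lapply(triplets, parse_one_symop)
  has_id <- any(vapply(ops, function(o) {
    all(o$R == diag(3)) && all(abs(o$t) < 1e-9)
  }, logical(1)))
  if (!has_id) ops <- c(list(list(R = diag(3L), t = c(0, 0, 0))), ops)
  structure(ops, class = "symops", triplets = triplets)
}

#' @export
print.symops <- function(x, ...) {
  cat(sprintf("%d symmetry operator(s)\n", length(x)))
  invisible(x)
}

.sg_table <- list(
  "P1"       = c("x,y,z"),
  "P2"       = c("x,y,z", "-x,y,-z"),
  "P21"      = c("x,y,z", "-x,y+1/2,-z"),
  "C2"       = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
  "P212121"  = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z")
)

#' Built-in symmetry operator sets for a few common space groups
#'
#' @param name One of `"P1"`, `"P2"`, `"P21"`, `"C2"`, `"P212121"` (spaces
#'   ignored, case-insensitive).
#' @return A [symops()] object.
#' @export
space_group_ops <- function(name) {
  key <- toupper(gsub("[[:space:]]", "", name))
  if (!key %in% names(.sg_table)) {
    stop_mrellg("unknown space group '", name, "'; supply explicit operators via symops()")
  }
  symops(.sg_table[[key]])
}

unique_rotations <- function(ops) {
  seen <- character(0)
  keep <- list()
  for (o in ops) {
    k <- paste(o$R, collapse = ",")
    if (!k %in% seen) {
      seen <- c(seen, k)
      keep[[length(keep) + 1L]] <- o$R
    }
  }
  keep
}

#' Centric flag and epsilon factor of a reflection
#'
#' A reflection is centric when some symmetry rotation maps `hkl` to `-hkl`
#' (its phase is then restricted); epsilon counts the rotations that fix
#' `hkl` and multiplies the expected intensity of the special reflection
#' class.
#'
#' @param ops A [symops()] object.
#' @param hkl Integer triple.
#' @return `list(centric = <logical>, epsilon = <integer >= 1>)`.
#' @export
centric_and_epsilon <- function(ops, hkl) {
  if (!inherits(ops, "symops") || length(ops) == 0) stop_mrellg("empty symmetry operator list")
  h <- as.numeric(hkl)
  if (length(h) != 3 || all(h == 0)) stop_mrellg("invalid reflection (0,0,0)")
  rots <- unique_rotations(ops)
  hR <- vapply(rots, function(R) as.numeric(h %*% R), numeric(3))
  centric <- any(colSums(hR == -h) == 3)
  eps <- sum(colSums(hR == h) == 3)
  list(centric = centric, epsilon = as.integer(eps))
}

#' Generate all Friedel-unique reflections to a resolution limit
#'
#' Enumerates every reflection with `d >= dmin`, keeps one representative per
#' Friedel pair (the one with `h > 0`, or `h = 0, k > 0`, or
#' `h = k = 0, l > 0`), and annotates each with its d-spacing, centric flag
#' and epsilon factor.
#'
#' @param cell A [unit_cell()].
#' @param ops A [symops()] object (defaults to P1).
#' @param dmin High-resolution limit in angstroms; must be positive.
#' @return A `reflection_set`: a data frame with columns `h, k, l, d,
#'   centric, epsilon` and attributes `cell`, `dmin`, `symops`.
#' @export
generate_reflections <- function(cell, ops = space_group_ops("P1"), dmin) {
  if (!is.numeric(dmin) || length(dmin) != 1 || !is.finite(dmin) || dmin <= 0) {
    stop_mrellg("dmin must be a positive number")
  }
  # conservative index bounds from the cell edges
  hmax <- floor(cell$a / dmin) + 1L
  kmax <- floor(cell$b / dmin) + 1L
  lmax <- floor(cell$c / dmin) + 1L
  grid <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  grid <- grid[!(grid$h == 0 & grid$k == 0 & grid$l == 0), , drop = FALSE]
  # Friedel-unique half
  keep <- grid$h > 0 | (grid$h == 0 & grid$k > 0) | (grid$h == 0 & grid$k == 0 & grid$l > 0)
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid)) {
    d <- d_spacing(cell, as.matrix(grid))
    grid <- grid[d >= dmin, , drop = FALSE]
    d <- d[d >= dmin]
  } else {
    d <- numeric(0)
  }
  rots <- unique_rotations(ops)
  n <- nrow(grid)
  centric <- logical(n)
  eps <- integer(n)
  if (n) {
    H <- as.matrix(grid)
    storage.mode(H) <- "double"
    cen <- matrix(FALSE, n, length(rots))
    fix <- matrix(FALSE, n, length(rots))
    for (j in seq_along(rots)) {
      HR <- H %*% rots[[j]]
      cen[, j] <- rowSums(HR == -H) == 3
      fix[, j] <- rowSums(HR == H) == 3
    }
    centric <- rowSums(cen) > 0
    eps <- as.integer(rowSums(fix))
  }
  out <- data.frame(h = grid$h, k = grid$k, l = grid$l, d = d,
                    centric = centric, epsilon = eps, row.names = NULL)
  ord <- order(-out$d, out$h, out$k, out$l)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("reflection_set", "data.frame"),
            cell = cell, dmin = dmin, symops = ops)
}

#' Read a cell/symmetry/resolution configuration
#'
#' Accepts a YAML or JSON file with fields `cell: [a, b, c, alpha, beta,
#' gamma]`, either `spacegroup: <name>` or `symops: [ "x,y,z", ... ]`, and
#' `dmin`.
#'
#' @param path Path to the configuration file.
#' @return `list(cell, symops, dmin)`.
#' @export
read_crystal_config <- function(path) {
  if (!file.exists(path)) stop_mrellg("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop_mrellg("yaml package required")
    yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE)) stop_mrellg("jsonlite package required")
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cl <- as.numeric(cfg$cell)
  if (length(cl) == 3) cl <- c(cl, 90, 90, 90)
  cell <- unit_cell(cl[1], cl[2], cl[3], cl[4], cl[5], cl[6])
  ops <- if (!is.null(cfg$symops)) symops(unlist(cfg$symops)) else {
    space_group_ops(cfg$spacegroup %||% "P1")
  }
  list(cell = cell, symops = ops, dmin = as.numeric(cfg$dmin %||% NA))
}
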