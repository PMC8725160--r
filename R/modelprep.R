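# Predicted-model preparation: strict PDB I/O, interpretation of per-residue
# coordinate-error estimates stored in the B-factor column, error-to-B
# conversion, error-threshold trimming, ensemble divergence trimming, and
# scattering-fraction estimation.

# ---- PDB parsing ------------------------------------------------------------

pdb_field <- function(lines, from, to) substr(lines, from, to)

parse_pdb_atoms <- function(lines, lineno) {
  short <- nchar(lines) < 66
  if (any(short)) {
    stop_mrellg("truncated ATOM record at line ", lineno[short][1],
                " (need at least 66 columns)")
  }
  num <- function(x, what, ln) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v))) stop_mrellg("unparseable ", what, " at line ", ln[is.na(v)][1])
    v
  }
  el <- trimws(pdb_field(lines, 77, 78))
  # infer element from the atom name when columns 77-78 are blank
  blank <- el == ""
  if (any(blank)) {
    nm <- trimws(pdb_field(lines[blank], 13, 16))
    el[blank] <- substr(gsub("[^A-Za-z].*", "", nm), 1, 1)
  }
  data.frame(
    chain = pdb_field(lines, 22, 22),
    resid = as.integer(num(pdb_field(lines, 23, 26), "residue number", lineno)),
    resname = trimws(pdb_field(lines, 18, 20)),
    atom = trimws(pdb_field(lines, 13, 16)),
    element = toupper(el),
    x = num(pdb_field(lines, 31, 38), "x coordinate", lineno),
    y = num(pdb_field(lines, 39, 46), "y coordinate", lineno),
    z = num(pdb_field(lines, 47, 54), "z coordinate", lineno),
    occ = num(pdb_field(lines, 55, 60), "occupancy", lineno),
    b = num(pdb_field(lines, 61, 66), "B factor", lineno),
    stringsAsFactors = FALSE
  )
}

#' Read a predicted model from a PDB file
#'
#' Parses standard fixed-column `ATOM`/`HETATM` records (orthogonal
#' angstroms) and an optional `CRYST1` cell. The B-factor column is
#' interpreted according to `mode`:
#' \describe{
#'   \item{`"delta"`}{B holds a predicted coordinate error Delta in
#'     angstroms (the CASP convention for predicted models); the per-residue
#'     Delta is taken from the residue's CA atom (first atom if no CA).}
#'   \item{`"plddt"`}{B holds pLDDT on a 0-100 scale; it is converted to an
#'     approximate Delta by the monotone mapping
#'     `Delta = 1.5 * exp(4 * (0.7 - pLDDT/100))` (an empirical
#'     approximation, clearly flagged as such).}
#'   \item{`"plain-b"`}{B is an ordinary displacement parameter; no Delta is
#'     attached.}
#' }
#'
#' @param path Path to a PDB file.
#' @param mode One of `"delta"`, `"plddt"`, `"plain-b"`.
#' @return An object of class `predicted_model`: `list(atoms, cell, mode)`
#'   where `atoms` is a data frame with orthogonal coordinates, `occ`, `b`
#'   and a per-residue `delta` column (NA in `"plain-b"` mode), and `cell`
#'   is a [unit_cell()] or `NULL`.
#' @export
read_model <- function(path, mode = c("delta", "plddt", "plain-b")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop_mrellg("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop_mrellg("no ATOM records in ", path)
  atoms <- parse_pdb_atoms(lines[is_atom], which(is_atom))
  cell <- NULL
  cr <- which(rec == "CRYST1")
  if (length(cr)) {
    ln <- lines[cr[1]]
    cv <- suppressWarnings(as.numeric(c(
      substr(ln, 7, 15), substr(ln, 16, 24), substr(ln, 25, 33),
      substr(ln, 34, 40), substr(ln, 41, 47), substr(ln, 48, 54))))
    if (any(is.na(cv))) stop_mrellg("unparseable CRYST1 record at line ", cr[1])
    cell <- unit_cell(cv[1], cv[2], cv[3], cv[4], cv[5], cv[6])
  }
  atoms$delta <- NA_real_
  if (mode != "plain-b") {
    key <- paste(atoms$chain, atoms$resid)
    for (k in unique(key)) {
      rows <- which(key == k)
      rep_row <- rows[match("CA", atoms$atom[rows])]
      if (is.na(rep_row)) rep_row <- rows[1]
      bval <- atoms$b[rep_row]
      delta <- if (mode == "delta") bval else plddt_to_delta(bval)
      if (!is.finite(delta) || delta < 0) {
        stop_mrellg("residue ", k, " has no interpretable error estimate (B = ", bval, ")")
      }
      atoms$delta[rows] <- delta
    }
  }
  structure(list(atoms = atoms, cell = cell, mode = mode),
            class = "predicted_model")
}

#' @export
print.predicted_model <- function(x, ...) {
  cat(sprintf("predicted model: %d atoms, %d residues, mode '%s'%s\n",
              nrow(x$atoms), nrow(residue_table(x)), x$mode,
              if (is.null(x$cell)) "" else ", with cell"))
  invisible(x)
}

#' Per-residue summary of a predicted model
#'
#' @param model A `predicted_model`.
#' @return Data frame with one row per residue: `chain`, `resid`, `delta`.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  key <- !duplicated(paste(a$chain, a$resid))
  data.frame(chain = a$chain[key], resid = a$resid[key], delta = a$delta[key])
}

#' Approximate conversion from pLDDT to a coordinate error in angstroms
#'
#' A documented monotone heuristic, `Delta = 1.5 * exp(4 * (0.7 -
#' pLDDT/100))`: about 0.45 angstroms at pLDDT 100, 1.5 at 70, and 5 near
#' 40. Real depositions store pLDDT rather than Delta; this mapping is an
#' approximation and is flagged as such.
#'
#' @param plddt Values on the 0-100 scale.
#' @return Estimated Delta in angstroms.
#' @export
plddt_to_delta <- function(plddt) {
  if (any(!is.finite(plddt)) || any(plddt < 0) || any(plddt > 100)) {
    stop_mrellg("pLDDT must lie in [0, 100]")
  }
  1.5 * exp(4 * (0.7 - plddt / 100))
}

#' Convert a predicted coordinate error to a B factor
#'
#' `B = 8 pi^2 Delta^2 / 3`: the isotropic displacement parameter whose
#' Debye-Waller factor matches a Gaussian positional error of r.m.s.
#' magnitude Delta. A Delta of 1 angstrom maps to about 26.3 square
#' angstroms.
#'
#' @param delta Predicted error(s) in angstroms, `>= 0`.
#' @return B factor(s) in square angstroms.
#' @export
error_to_bfactor <- function(delta) {
  if (any(!is.finite(delta)) || any(delta < 0)) stop_mrellg("delta must be >= 0")
  8 * pi^2 * delta^2 / 3
}

#' Trim a predicted model by its per-residue error estimate
#'
#' Removes every residue whose predicted error Delta exceeds the threshold,
#' preserving atom order otherwise. Thresholds in the 0.7-1.2 angstrom range
#' are typical for preparing predicted models for molecular replacement.
#'
#' @param model A `predicted_model` read in `"delta"` or `"plddt"` mode.
#' @param threshold Error threshold in angstroms, `> 0`.
#' @return The trimmed `predicted_model`, with attribute
#'   `retained_fraction` (fraction of residues kept).
#' @export
trim_by_error <- function(model, threshold) {
  if (!inherits(model, "predicted_model")) stop_mrellg("not a predicted_model")
  if (model$mode == "plain-b") stop_mrellg("model has no error estimates (mode 'plain-b')")
  if (!is.finite(threshold) || threshold <= 0) stop_mrellg("threshold must be positive")
  keep <- model$atoms$delta <= threshold
  if (!any(keep)) stop_mrellg("trimming at ", threshold, " A removes every residue")
  res_before <- nrow(residue_table(model))
  model$atoms <- model$atoms[keep, , drop = FALSE]
  rownames(model$atoms) <- NULL
  structure(model, retained_fraction = nrow(residue_table(model)) / res_before)
}

#' Build an ensemble of predicted models
#'
#' Reduces all members to their common core (the intersection of
#' chain/residue identifiers) so that members share a residue numbering.
#'
#' @param ... Two or more `predicted_model` objects, or a single list of
#'   them.
#' @return An object of class `ensemble` (a list of reduced members).
#' @export
ensemble <- function(...) {
  members <- list(...)
  if (length(members) == 1 && !inherits(members[[1]], "predicted_model")) {
    members <- members[[1]]
  }
  if (length(members) < 2) stop_mrellg("an ensemble needs at least 2 members")
  keys <- lapply(members, function(m) paste(m$atoms$chain, m$atoms$resid))
  common <- Reduce(intersect, lapply(keys, unique))
  if (!length(common)) stop_mrellg("members share no residues")
  members <- Map(function(m, k) {
    m$atoms <- m$atoms[k %in% common, , drop = FALSE]
    rownames(m$atoms) <- NULL
    m
  }, members, keys)
  structure(members, class = "ensemble")
}

member_ca <- function(m) {
  a <- m$atoms[m$atoms$atom == "CA", , drop = FALSE]
  if (!nrow(a)) a <- m$atoms[!duplicated(paste(m$atoms$chain, m$atoms$resid)), , drop = FALSE]
  a
}

#' Trim an ensemble by inter-member divergence
#'
#' Superposes every member onto the first (least-squares, over common-core
#' CA atoms), computes the per-residue maximum pairwise CA divergence, and
#' removes residues exceeding the threshold from all members. For
#' tightly-consistent predicted models only exceptionally small thresholds
#' (of order 0.1 angstroms) mark anything.
#'
#' @param ens An [ensemble()].
#' @param divergence_threshold Per-residue divergence threshold in
#'   angstroms.
#' @return The trimmed ensemble, with attribute `divergence` (the
#'   per-residue maximum pairwise divergence used).
#' @export
ensemble_divergence_trim <- function(ens, divergence_threshold) {
  if (!inherits(ens, "ensemble") || length(ens) < 2) {
    stop_mrellg("need an ensemble of >= 2 members")
  }
  cas <- lapply(ens, member_ca)
  key0 <- paste(cas[[1]]$chain, cas[[1]]$resid)
  coords <- lapply(cas, function(a) {
    m <- as.matrix(a[match(key0, paste(a$chain, a$resid)), c("x", "y", "z")])
    rownames(m) <- NULL
    m
  })
  aligned <- vector("list", length(coords))
  aligned[[1]] <- coords[[1]]
  for (i in seq_along(coords)[-1]) {
    sp <- superpose(coords[[i]], coords[[1]])
    aligned[[i]] <- apply_superposition(sp, coords[[i]])
  }
  n <- nrow(coords[[1]])
  div <- numeric(n)
  for (i in seq_along(aligned)) {
    for (j in seq_along(aligned)) {
      if (j <= i) next
      d <- sqrt(rowSums((aligned[[i]] - aligned[[j]])^2))
      div <- pmax(div, d)
    }
  }
  drop_keys <- key0[div > divergence_threshold]
  out <- lapply(ens, function(m) {
    k <- paste(m$atoms$chain, m$atoms$resid)
    m$atoms <- m$atoms[!k %in% drop_keys, , drop = FALSE]
    if (!nrow(m$atoms)) stop_mrellg("divergence trimming removed every residue")
    rownames(m$atoms) <- NULL
    m
  })
  structure(out, class = "ensemble", divergence = stats::setNames(div, key0))
}

#' Estimate the scattering fraction fm of a model
#'
#' `sum((occ * f)^2)` over the model's atoms divided by the total scattering
#' of the full asymmetric-unit contents, with point-atom `f` (atomic
#' number). Values above 1 indicate an inconsistent composition and raise an
#' error.
#'
#' @param model A `predicted_model` or [atomic_model()].
#' @param asu_total_scattering Total `sum(f^2)` of the asymmetric unit
#'   (e.g. from [sequence_scattering()] times the number of copies).
#' @return The scattering fraction in `[0, 1]`.
#' @export
estimate_fm <- function(model, asu_total_scattering) {
  if (!is.finite(asu_total_scattering) || asu_total_scattering <= 0) {
    stop_mrellg("asu_total_scattering must be positive")
  }
  atoms <- if (inherits(model, "predicted_model")) model$atoms else model
  sc <- sum((atoms$occ * scattering_factor(atoms$element))^2)
  if (sc > asu_total_scattering * (1 + 1e-9)) {
    stop_mrellg("model scattering exceeds the stated asymmetric-unit total")
  }
  min(1, sc / asu_total_scattering)
}

# Heavy-atom counts (C, N, O, S) per amino-acid residue, protein backbone
# included; hydrogens are omitted as in typical deposited models.
.aa_composition <- list(
  A = c(C = 3, N = 1, O = 1), R = c(C = 6, N = 4, O = 1), N = c(C = 4, N = 2, O = 2),
  D = c(C = 4, N = 1, O = 3), C = c(C = 3, N = 1, O = 1, S = 1),
  E = c(C = 5, N = 1, O = 3), Q = c(C = 5, N = 2, O = 2), G = c(C = 2, N = 1, O = 1),
  H = c(C = 6, N = 3, O = 1), I = c(C = 6, N = 1, O = 1), L = c(C = 6, N = 1, O = 1),
  K = c(C = 6, N = 2, O = 1), M = c(C = 5, N = 1, O = 1, S = 1),
  F = c(C = 9, N = 1, O = 1), P = c(C = 5, N = 1, O = 1), S = c(C = 3, N = 1, O = 2),
  T = c(C = 4, N = 1, O = 2), W = c(C = 11, N = 2, O = 1), Y = c(C = 9, N = 1, O = 2),
  V = c(C = 5, N = 1, O = 1)
)

#' Total scattering of a protein sequence
#'
#' `sum(f^2)` over the heavy atoms of a one-letter-code sequence (point-atom
#' `f`), for use as the asymmetric-unit total in [estimate_fm()]. Accepts a
#' raw sequence string or a FASTA file path.
#'
#' @param seq One-letter amino-acid sequence, or path to a FASTA file.
#' @param copies Number of copies in the asymmetric unit.
#' @return Total `sum(f^2)`.
#' @export
sequence_scattering <- function(seq, copies = 1) {
  if (length(seq) == 1 && file.exists(seq)) {
    lines <- readLines(seq, warn = FALSE)
    seq <- paste(lines[!grepl("^>", lines)], collapse = "")
  }
  aa <- strsplit(toupper(gsub("[^A-Za-z]", "", seq)), "")[[1]]
  bad <- setdiff(aa, names(.aa_composition))
  if (length(bad)) stop_mrellg("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  per_res <- vapply(aa, function(r) {
    comp <- .aa_composition[[r]]
    sum(comp * scattering_factor(names(comp))^2)
  }, numeric(1))
  copies * sum(per_res)
}

#' Write a predicted model as a PDB file
#'
#' Standard fixed-column `ATOM` records (orthogonal angstroms), preceded by a
#' `CRYST1` record when the model carries a cell. With
#' `b_policy = "delta-converted"` the B column holds `8 pi^2 Delta^2 / 3`;
#' with `"original"` it holds the values read in.
#'
#' @param model A `predicted_model`.
#' @param path Output path.
#' @param b_policy `"original"` or `"delta-converted"`.
#' @return The path, invisibly.
#' @export
write_model <- function(model, path, b_policy = c("original", "delta-converted")) {
  b_policy <- match.arg(b_policy)
  if (!inherits(model, "predicted_model") || nrow(model$atoms) == 0) {
    stop_mrellg("refusing to write an empty or invalid model")
  }
  a <- model$atoms
  bcol <- if (b_policy == "delta-converted") {
    if (any(is.na(a$delta))) stop_mrellg("delta-converted policy needs error estimates")
    error_to_bfactor(a$delta)
  } else {
    a$b
  }
  lines <- character(0)
  if (!is.null(model$cell)) {
    cl <- model$cell
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma)
  }
  name4 <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom), a$atom)
  lines <- c(lines, sprintf(
    "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name4, a$resname, a$chain, a$resid,
    a$x, a$y, a$z, a$occ, bcol, a$element), "END")
  writeLines(lines, path)
  invisible(path)
}
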