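#' Binding-mode and flexibility comparison metrics
#'
#' A binding mode is the vector of per-residue (and cofactor) interaction
#' energies describing how a ligand engages a pocket. Two modes are compared
#' over the union of their residue identifiers, with residues contacted by
#' only one ligand contributing their full energy ("all bindings included":
#' no interaction means zero energy). Crystallographic flexibility is
#' compared through z-scored B-factor profiles.
#'
#' @name compare
NULL

#' Construct a binding mode
#'
#' @param ligand_id ligand name.
#' @param energies named numeric vector: residue/cofactor identifier ->
#'   interaction energy in kJ/mol (stabilizing interactions negative).
#' @return Object of class `binding_mode`.
#' @export
binding_mode <- function(ligand_id, energies) {
  if (is.null(names(energies)) && length(energies)) {
    stop("`energies` must be named by residue identifier", call. = FALSE)
  }
  if (anyDuplicated(names(energies))) {
    stop("duplicate residue identifiers: ",
         paste(unique(names(energies)[duplicated(names(energies))]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(energies))) {
    stop("interaction energies must be finite", call. = FALSE)
  }
  structure(list(ligand_id = as.character(ligand_id),
                 entries = energies), class = "binding_mode")
}

.mode_diff <- function(P, Q) {
  p <- if (inherits(P, "binding_mode")) P$entries else P
  q <- if (inherits(Q, "binding_mode")) Q$entries else Q
  ids <- union(names(p), names(q))
  if (!length(ids)) stop("both binding modes are empty", call. = FALSE)
  pv <- ifelse(ids %in% names(p), p[ids], 0)
  qv <- ifelse(ids %in% names(q), q[ids], 0)
  pv[is.na(pv)] <- 0; qv[is.na(qv)] <- 0
  list(d = pv - qv, n = length(ids))
}

#' Root mean square deviation between binding modes
#'
#' `RMSD_BM(P, Q) = sqrt(mean((p_i - q_i)^2))` over the union of residue
#' identifiers with zero-fill for absent entries.
#'
#' @param P,Q [binding_mode()] objects or named energy vectors (kJ/mol).
#' @return RMSD in kJ/mol.
#' @examples
#' rmsd_bm(c(r1 = -4, r2 = 0), c(r1 = 0, r2 = 3)) # 3.536
#' @export
rmsd_bm <- function(P, Q) {
  md <- .mode_diff(P, Q)
  sqrt(sum(md$d^2) / md$n)
}

#' Manhattan or Euclidean distance between binding modes
#'
#' Same union/zero-fill convention as [rmsd_bm()]. For every input,
#' `manhattan >= euclidean` (norm inequality).
#'
#' @inheritParams rmsd_bm
#' @param metric `"manhattan"` or `"euclidean"`.
#' @return Distance in kJ/mol.
#' @export
mode_distance <- function(P, Q, metric = c("manhattan", "euclidean")) {
  metric <- match.arg(metric)
  md <- .mode_diff(P, Q)
  switch(metric,
         manhattan = sum(abs(md$d)),
         euclidean = sqrt(sum(md$d^2)))
}

#' Normalize a B-factor profile to B' z-scores
#'
#' `B'_i = (B_i - mean(B)) / sd_pop(B)` with the population standard
#' deviation, so the output has mean 0 and (population) SD 1. Negative B'
#' marks residues more rigid than the structure average.
#'
#' @param profile named numeric vector of per-residue B-factors (A^2),
#'   length >= 2.
#' @return Named numeric vector of dimensionless B' values.
#' @examples
#' normalize_bfactors(c(a = 10, b = 20, c = 30))
#' @export
normalize_bfactors <- function(profile) {
  b <- as.numeric(profile)
  if (length(b) < 2L) {
    stop("need at least 2 residues to normalize", call. = FALSE)
  }
  if (any(!is.finite(b))) stop("B-factors must be finite", call. = FALSE)
  sd_pop <- sqrt(mean((b - mean(b))^2))
  if (sd_pop == 0) {
    stop("constant B-factor profile: zero variance, B' undefined",
         call. = FALSE)
  }
  out <- (b - mean(b)) / sd_pop
  names(out) <- names(profile)
  out
}

#' Per-residue difference of normalized B-factors
#'
#' Normalizes both profiles with [normalize_bfactors()] and differences them
#' over aligned residues: `dB'_i = B'_a,i - B'_b,i`. By default residues are
#' aligned by identical names (identifiers present in both profiles); an
#' explicit two-column alignment overrides.
#'
#' @param a,b named numeric B-factor profiles (A^2).
#' @param alignment optional data frame / matrix with two columns giving
#'   paired residue identifiers of `a` and `b`.
#' @param window width (in residues) for the rolling mean-absolute-deviation
#'   summary; `NULL` for none.
#' @return List of class `delta_bprime`: `delta` (named numeric), `mad`
#'   (mean absolute deviation), and `window_mad` (data frame, when `window`
#'   given).
#' @export
delta_bfactors <- function(a, b, alignment = NULL, window = NULL) {
  ba <- normalize_bfactors(a)
  bb <- normalize_bfactors(b)
  if (is.null(alignment)) {
    ids <- intersect(names(ba), names(bb))
    alignment <- cbind(ids, ids)
  }
  alignment <- as.matrix(alignment)
  if (!nrow(alignment)) stop("empty residue alignment", call. = FALSE)
  if (!all(alignment[, 1L] %in% names(ba)) ||
      !all(alignment[, 2L] %in% names(bb))) {
    stop("alignment refers to residues absent from a profile", call. = FALSE)
  }
  delta <- ba[alignment[, 1L]] - bb[alignment[, 2L]]
  names(delta) <- alignment[, 1L]
  out <- list(delta = delta, mad = mean(abs(delta)))
  if (!is.null(window)) {
    w <- as.integer(window)
    if (w < 1L || w > length(delta)) {
      stop("`window` must be between 1 and the alignment length", call. = FALSE)
    }
    starts <- seq_len(length(delta) - w + 1L)
    out$window_mad <- data.frame(
      start = names(delta)[starts],
      mad = vapply(starts, function(s) mean(abs(delta[s:(s + w - 1L)])),
                   numeric(1L)))
  }
  structure(out, class = "delta_bprime")
}

#' Extract a per-residue B-factor profile from a PDB file
#'
#' Reads the B-factor column of the ATOM records (via bio3d) and averages it
#' per residue, optionally restricted to one chain or to C-alpha atoms.
#'
#' @param path PDB file path.
#' @param chain optional chain identifier.
#' @param calpha use only C-alpha atoms (default `TRUE`).
#' @return Named numeric vector (names `chain:resno`) of B-factors.
#' @export
read_bfactor_profile <- function(path, chain = NULL, calpha = TRUE) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (calpha) at <- at[at$elety == "CA", , drop = FALSE]
  if (!nrow(at)) stop("no matching ATOM records in ", path, call. = FALSE)
  key <- paste0(at$chain, ":", at$resno)
  tapply(at$b, factor(key, levels = unique(key)), mean)
}
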