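#' Structure-binding strength indices (SBSI)
#'
#' Each index contrasts one docking energy term between a reference ligand
#' and a candidate, scaled by their structural dissimilarity:
#' `index = (term_reference - term_ligand) / (1 - s)`, with `s` a molecular
#' similarity in \[0, 1\]. The seven terms are binding affinity (SBAI),
#' hydrogen bonds (SHBI), steric (SSEI), protein-ligand (SPLI), van der Waals
#' (SVdWI), RNA template (SRNAI) and metal cofactors (SMEI). For a ligand
#' identical to the reference (`s = 1`) the indices are infinitely large; the
#' package returns signed `Inf` (positive for a zero numerator) rather than a
#' large float.
#'
#' @name sbsi
NULL

sbsi_terms <- c(sbai = "binding_affinity", shbi = "hydrogen_bonds",
                ssei = "steric", spli = "protein_ligand", svdwi = "vdw",
                srnai = "rna_template", smei = "metal")

#' Docking energy decomposition for one ligand
#'
#' @param ligand_id ligand name.
#' @param binding_affinity,protein_ligand,steric,hydrogen_bonds,vdw,metal,rna_template,total
#'   energy terms in kJ/mol (any may be `NA` if unavailable).
#' @return A one-row data frame of class `energy_decomposition`.
#' @export
energy_decomposition <- function(ligand_id, binding_affinity = NA_real_,
                                 protein_ligand = NA_real_, steric = NA_real_,
                                 hydrogen_bonds = NA_real_, vdw = NA_real_,
                                 metal = NA_real_, rna_template = NA_real_,
                                 total = NA_real_) {
  vals <- c(binding_affinity = binding_affinity, protein_ligand = protein_ligand,
            steric = steric, hydrogen_bonds = hydrogen_bonds, vdw = vdw,
            metal = metal, rna_template = rna_template, total = total)
  if (any(is.infinite(vals) | is.nan(vals), na.rm = TRUE)) {
    stop("energy terms must be finite or NA", call. = FALSE)
  }
  out <- data.frame(ligand_id = as.character(ligand_id), t(vals),
                    stringsAsFactors = FALSE)
  class(out) <- c("energy_decomposition", class(out))
  out
}

#' Similarity scores of one ligand against the reference
#'
#' @param ligand_id ligand name.
#' @param tanimoto,atom_pair,mcs similarities in \[0, 1\].
#' @return A one-row data frame of class `similarity_scores`.
#' @export
similarity_scores <- function(ligand_id, tanimoto = NA_real_,
                              atom_pair = NA_real_, mcs = NA_real_) {
  vals <- c(tanimoto = tanimoto, atom_pair = atom_pair, mcs = mcs)
  bad <- !is.na(vals) & (vals < 0 | vals > 1)
  if (any(bad)) {
    stop("similarity out of [0, 1]: ", names(vals)[bad][1L], " = ",
         vals[bad][1L], call. = FALSE)
  }
  out <- data.frame(ligand_id = as.character(ligand_id), t(vals),
                    stringsAsFactors = FALSE)
  class(out) <- c("similarity_scores", class(out))
  out
}

#' A single structure-binding strength index
#'
#' `(reference_term - ligand_term) / (1 - similarity)`; `Inf`/`-Inf` (sign of
#' the numerator, `+Inf` for a zero numerator) when `similarity == 1`.
#'
#' @param reference_term,ligand_term energies in kJ/mol.
#' @param similarity structural similarity in \[0, 1\].
#' @return Index in kJ/mol (possibly infinite), vectorized.
#' @examples
#' sbsi_index(-50.34, -71.98, 0.4342) # 38.2 kJ/mol
#' @export
sbsi_index <- function(reference_term, ligand_term, similarity) {
  if (any(!is.finite(similarity)) || any(similarity < 0) || any(similarity > 1)) {
    stop("similarity must lie in [0, 1], got ",
         similarity[which(similarity < 0 | similarity > 1 |
                            !is.finite(similarity))[1L]], call. = FALSE)
  }
  num <- reference_term - ligand_term
  out <- ifelse(similarity == 1, ifelse(num >= 0, Inf, -Inf),
                num / (1 - similarity))
  unname(out)
}

#' All seven SBSI indices for one ligand against the reference
#'
#' @param reference,ligand [energy_decomposition()] rows sharing the term
#'   schema.
#' @param scores a [similarity_scores()] row for the ligand.
#' @param similarity_kind one of `"tanimoto"`, `"atom_pair"`, `"mcs"`.
#' @return A one-row data frame of class `sbsi_record` with columns
#'   `ligand_id`, `similarity_kind`, `similarity`, `sbai`, `shbi`, `ssei`,
#'   `spli`, `svdwi`, `srnai`, `smei`. Missing energy terms yield `NA`
#'   indices with a warning, never silent zeros.
#' @export
sbsi_all <- function(reference, ligand, scores,
                     similarity_kind = c("tanimoto", "atom_pair", "mcs")) {
  similarity_kind <- match.arg(similarity_kind)
  s <- scores[[similarity_kind]][1L]
  if (is.na(s)) {
    stop("similarity of kind `", similarity_kind, "` is missing for ",
         scores$ligand_id[1L], call. = FALSE)
  }
  vals <- vapply(sbsi_terms, function(term) {
    rt <- reference[[term]][1L]
    lt <- ligand[[term]][1L]
    if (is.na(rt) || is.na(lt)) return(NA_real_)
    sbsi_index(rt, lt, s)
  }, numeric(1L))
  if (anyNA(vals)) {
    warning("missing energy term(s) for ", ligand$ligand_id[1L], ": ",
            paste(sbsi_terms[is.na(vals)], collapse = ", "),
            "; corresponding indices reported as NA", call. = FALSE)
  }
  out <- data.frame(ligand_id = ligand$ligand_id[1L],
                    similarity_kind = similarity_kind, similarity = s,
                    t(vals), stringsAsFactors = FALSE)
  class(out) <- c("sbsi_record", class(out))
  out
}

#' Classify a ligand by its structure-binding affinity index
#'
#' Ligands with `sbai > 0` (or infinite, i.e. identical to the reference)
#' bind more strongly than the reference per unit structural dissimilarity
#' and are classified `"strongly_binding"` (active); `sbai < 0` gives
#' `"weakly_binding"` (non-active). An exact zero is classified
#' strongly_binding with a boundary warning.
#'
#' @param x an `sbsi_record` from [sbsi_all()], or a numeric SBAI value.
#' @return `"strongly_binding"` or `"weakly_binding"`.
#' @export
sbsi_classify <- function(x) {
  sbai <- if (is.numeric(x)) x[1L] else x$sbai[1L]
  if (is.na(sbai)) stop("SBAI is missing; cannot classify", call. = FALSE)
  if (sbai == 0) {
    warning("SBAI is exactly 0: on the active/non-active boundary; ",
            "classified strongly_binding", call. = FALSE)
    return("strongly_binding")
  }
  if (sbai > 0) "strongly_binding" else "weakly_binding"
}

#' SBSI screening table for a panel of ligands
#'
#' Convenience wrapper applying [sbsi_all()] and [sbsi_classify()] to every
#' non-reference ligand in an energy table.
#'
#' @param energies data frame of [energy_decomposition()] rows (one per
#'   ligand).
#' @param similarities data frame of [similarity_scores()] rows.
#' @param reference ligand_id of the reference compound.
#' @param similarity_kind forwarded to [sbsi_all()].
#' @return Data frame with one `sbsi_record` row per non-reference ligand
#'   plus a `class` column, ordered by decreasing `sbai`.
#' @export
sbsi_screen <- function(energies, similarities, reference,
                        similarity_kind = c("tanimoto", "atom_pair", "mcs")) {
  similarity_kind <- match.arg(similarity_kind)
  if (!reference %in% energies$ligand_id) {
    stop("reference ligand `", reference, "` not found in the energy table",
         call. = FALSE)
  }
  ref <- energies[energies$ligand_id == reference, , drop = FALSE]
  others <- setdiff(energies$ligand_id, reference)
  rows <- lapply(others, function(id) {
    sc <- similarities[similarities$ligand_id == id, , drop = FALSE]
    if (!nrow(sc)) {
      stop("no similarity scores for ligand `", id, "`", call. = FALSE)
    }
    rec <- sbsi_all(ref, energies[energies$ligand_id == id, , drop = FALSE],
                    sc, similarity_kind)
    rec$class <- sbsi_classify(rec)
    rec
  })
  out <- do.call(rbind, rows)
  out[order(-out$sbai), , drop = FALSE]
}
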