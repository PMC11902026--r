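#' Readers and writers for the toolkit's tabular formats
#'
#' All readers accept comma-separated UTF-8 files with a header row and "."
#' as decimal separator; Unicode minus signs (as pasted from publications)
#' are normalized to ASCII on read. Missing required columns are rejected
#' with a diagnostic naming the file and column.
#'
#' @name quadbind-io
NULL

.normalize_minus <- function(x) {
  if (is.character(x)) gsub("[−–]", "-", x) else x
}

.read_csv <- function(path, required, label) {
  if (!file.exists(path)) stop(label, " file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df[] <- lapply(df, .normalize_minus)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(label, " file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- setdiff(required, c("site", "compound", "context", "ligand_id",
                             "structure", "residue_id", "channel", "term",
                             "assignment"))
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & nzchar(trimws(df[[cn]])))
    if (length(bad)) {
      stop(label, " file ", path, ", line ", bad[1L] + 1L,
           ": non-numeric value in column `", cn, "`", call. = FALSE)
    }
    df[[cn]] <- v
  }
  df
}

#' Read a per-site frequency table
#'
#' Columns `site`, `nu_plus`, `nu_minus` and optionally `nu_zero` (derived
#' as `nu_plus - nu_minus` when absent). JSON files (array of objects with
#' the same fields) are accepted too.
#'
#' @param path CSV or JSON file.
#' @param check_consistency tolerance (MHz) for `|nu_zero - (nu_plus -
#'   nu_minus)|` when `nu_zero` is present; `NULL` disables the check.
#' @return Data frame with columns `site`, `nu_plus`, `nu_minus`, `nu_zero`.
#' @export
read_frequency_table <- function(path, check_consistency = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::fromJSON(path))
    missing <- setdiff(c("site", "nu_plus", "nu_minus"), names(df))
    if (length(missing)) {
      stop("frequency JSON ", path, " lacks field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  } else {
    df <- .read_csv(path, c("site", "nu_plus", "nu_minus"), "frequency")
  }
  if (is.null(df$nu_zero)) df$nu_zero <- df$nu_plus - df$nu_minus
  df$nu_zero <- suppressWarnings(as.numeric(df$nu_zero))
  df$nu_zero[is.na(df$nu_zero)] <-
    (df$nu_plus - df$nu_minus)[is.na(df$nu_zero)]
  if (!is.null(check_consistency)) {
    dev <- abs(df$nu_zero - (df$nu_plus - df$nu_minus))
    if (any(dev > check_consistency)) {
      i <- which.max(dev)
      stop("inconsistent triplet for site ", df$site[i], ": nu_zero deviates ",
           "by ", signif(dev[i], 3), " MHz", call. = FALSE)
    }
  }
  df[c("site", "nu_plus", "nu_minus", "nu_zero")]
}

#' Read a per-site NQR parameter table
#'
#' Columns `site`, `cqcc`, `eta`.
#'
#' @param path CSV file.
#' @return An [nqr_params()] data frame.
#' @export
read_params_table <- function(path) {
  df <- .read_csv(path, c("site", "cqcc", "eta"), "parameter")
  nqr_params(df$cqcc, df$eta, site = df$site)
}

#' Read EFG tensors from JSON
#'
#' Expects an object (or array of objects) with fields `site` and
#' `components` (3x3 nested array, atomic units).
#'
#' @param path JSON file.
#' @return Named list of 3x3 matrices.
#' @export
read_efg_json <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!is.null(js$site) && !is.null(js$components)) js <- list(js)
  out <- lapply(js, function(entry) {
    m <- entry$components
    if (is.list(m)) m <- do.call(rbind, m)
    m <- as.matrix(m)
    if (!all(dim(m) == c(3L, 3L))) {
      stop("EFG tensor in ", path, " is not 3x3", call. = FALSE)
    }
    m
  })
  names(out) <- vapply(js, function(entry) {
    if (is.null(entry$site)) NA_character_ else as.character(entry$site)
  }, character(1L))
  out
}

#' Read a per-context NQR parameter table
#'
#' Long format with columns `compound`, `site`, `context` (one of `single`,
#' `solid`, `complex`), `cqcc`, `eta`; one [context_params()] is assembled
#' per (compound, site).
#'
#' @param path CSV file.
#' @param aliases optional named character vector mapping site labels to a
#'   common label before grouping (explicit cross-site comparisons).
#' @return Named list (by `compound: site`) of [context_params()].
#' @export
read_context_table <- function(path, aliases = NULL) {
  df <- .read_csv(path, c("compound", "site", "context", "cqcc", "eta"),
                  "context parameter")
  bad <- !df$context %in% c("single", "solid", "complex")
  if (any(bad)) {
    stop("unknown context `", df$context[which(bad)[1L]], "` in ", path,
         " (expected single/solid/complex)", call. = FALSE)
  }
  if (!is.null(aliases)) {
    hit <- df$site %in% names(aliases)
    df$site[hit] <- aliases[df$site[hit]]
  }
  key <- paste(df$compound, df$site, sep = ": ")
  out <- lapply(split(df, factor(key, levels = unique(key))), function(d) {
    if (anyDuplicated(d$context)) {
      stop("duplicate context `", d$context[duplicated(d$context)][1L],
           "` for ", d$compound[1L], " site ", d$site[1L], call. = FALSE)
    }
    args <- list(site_label = d$site[1L])
    for (i in seq_len(nrow(d))) args[[d$context[i]]] <- c(d$cqcc[i], d$eta[i])
    do.call(context_params, args)
  })
  out
}

#' Read a docking energy decomposition table
#'
#' Wide layout: a `term` column plus one column per ligand. Recognized terms
#' (case-insensitive): total, protein_ligand, steric, hydrogen_bonds, vdw,
#' metal, rna_template, binding_affinity.
#'
#' @param path CSV file.
#' @return Data frame of [energy_decomposition()] rows (one per ligand).
#' @export
read_energy_table <- function(path) {
  df <- .read_csv(path, "term", "energy decomposition")
  terms <- tolower(trimws(df$term))
  known <- c("total", "protein_ligand", "steric", "hydrogen_bonds", "vdw",
             "metal", "rna_template", "binding_affinity")
  bad <- setdiff(terms, known)
  if (length(bad)) {
    stop("unknown energy term(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ligands <- setdiff(names(df), "term")
  rows <- lapply(ligands, function(lig) {
    v <- suppressWarnings(as.numeric(.normalize_minus(df[[lig]])))
    args <- stats::setNames(as.list(v), terms)
    args$ligand_id <- lig
    do.call(energy_decomposition, args)
  })
  do.call(rbind, rows)
}

#' Read a ligand similarity table
#'
#' Columns `ligand_id` plus any of `tanimoto`, `atom_pair`, `mcs`.
#'
#' @param path CSV file.
#' @return Data frame of [similarity_scores()] rows.
#' @export
read_similarity_table <- function(path) {
  df <- .read_csv(path, "ligand_id", "similarity")
  rows <- lapply(seq_len(nrow(df)), function(i) {
    similarity_scores(
      df$ligand_id[i],
      tanimoto = if (!is.null(df$tanimoto))
        suppressWarnings(as.numeric(df$tanimoto[i])) else NA_real_,
      atom_pair = if (!is.null(df$atom_pair))
        suppressWarnings(as.numeric(df$atom_pair[i])) else NA_real_,
      mcs = if (!is.null(df$mcs))
        suppressWarnings(as.numeric(df$mcs[i])) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Read a contact-percentage matrix
#'
#' Square CSV: first column element symbols, remaining columns one per
#' element; empty cells are zero.
#'
#' @param path CSV file.
#' @param ... forwarded to [contact_matrix()].
#' @return A [contact_matrix()].
#' @export
read_contact_csv <- function(path, ...) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  el <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  m <- apply(m, 2L, function(col) {
    suppressWarnings(as.numeric(.normalize_minus(col)))
  })
  rownames(m) <- el
  contact_matrix(m, elements = el, structure_id = basename(path), ...)
}

#' Read a contribution vector (channel, value)
#'
#' @param path CSV file with columns `channel`, `value`.
#' @return Named numeric vector.
#' @export
read_contribution_csv <- function(path) {
  df <- .read_csv(path, c("channel", "value"), "contribution")
  stats::setNames(df$value, df$channel)
}

#' Read a binding mode (residue_id, energy)
#'
#' @param path CSV file with columns `residue_id`, `energy`.
#' @param ligand_id ligand name (defaults to the file name).
#' @return A [binding_mode()].
#' @export
read_binding_mode_csv <- function(path, ligand_id = NULL) {
  df <- .read_csv(path, c("residue_id", "energy"), "binding mode")
  binding_mode(if (is.null(ligand_id)) basename(path) else ligand_id,
               stats::setNames(df$energy, df$residue_id))
}

#' Write a data frame as CSV (full precision, no row names)
#'
#' @param x data frame.
#' @param path output file or `""` for stdout.
#' @return `x`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, file = path, row.names = FALSE, quote = TRUE)
  invisible(x)
}
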