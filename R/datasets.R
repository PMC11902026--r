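#' Bundled reference data
#'
#' Small plain-text tables shipped with the package: the experimental 14N
#' NQR frequency sets of ribavirin (form II, 295 K) and of its aglycone
#' building block 1H-1,2,4-triazole, ligand-vs-ribavirin similarity scores,
#' the docking energy decomposition and binding affinities of the six-ligand
#' panel, per-context NQR parameters (single molecule / solid / complex)
#' from quantum-chemical calculations, nitrogen-site Hirshfeld contact
#' contributions, and standard SMILES for the ligand panel.
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return `quadbind_example()` returns a path (or the available file
#'   names); the loaders below return parsed objects.
#' @export
quadbind_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "quadbind")))
  }
  path <- system.file("extdata", file, package = "quadbind")
  if (!nzchar(path)) stop("no bundled file `", file, "`", call. = FALSE)
  path
}

#' @rdname quadbind_example
#' @export
ribavirin_nqr_table <- function() {
  utils::read.csv(quadbind_example("ribavirin_nqr_frequencies.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname quadbind_example
#' @export
triazole_nqr_table <- function() {
  utils::read.csv(quadbind_example("triazole_nqr_frequencies.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname quadbind_example
#' @export
ligand_similarity_table <- function() {
  read_similarity_table(quadbind_example("ligand_similarities.csv"))
}

#' @rdname quadbind_example
#' @export
docking_energy_table <- function() {
  read_energy_table(quadbind_example("docking_energies.csv"))
}

#' @rdname quadbind_example
#' @param aliases forwarded to [read_context_table()].
#' @export
nqr_context_table <- function(aliases = NULL) {
  read_context_table(quadbind_example("nqr_site_params.csv"),
                     aliases = aliases)
}

#' @rdname quadbind_example
#' @export
nitrogen_contact_table <- function() {
  df <- utils::read.csv(quadbind_example("nitrogen_contacts.csv"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  channels <- setdiff(names(df), "structure")
  out <- lapply(seq_len(nrow(df)), function(i) {
    v <- suppressWarnings(as.numeric(df[i, channels]))
    names(v) <- channels
    v
  })
  names(out) <- df$structure
  out
}

#' @rdname quadbind_example
#' @export
ligand_smiles <- function() {
  lines <- readLines(quadbind_example("ligand_smiles.smi"))
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  stats::setNames(vapply(parts, `[`, character(1L), 2L),
                  vapply(parts, `[`, character(1L), 1L))
}
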