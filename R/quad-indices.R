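#' Quadrupolar indices: solid-state, complexation and solid-vs-complex shifts
#'
#' The electron density at a nitrogen nucleus, summarized by its quadrupole
#' coupling constant and asymmetry parameter, shifts when the isolated
#' molecule is packed into a crystal or bound inside a protein pocket. Six
#' paired indices quantify those shifts per site:
#' \describe{
#'   \item{Delta_s, delta_s}{solid state minus single molecule (cqcc, eta)}
#'   \item{Delta_c, delta_c}{protein-ligand complex minus single molecule}
#'   \item{Delta_cs, delta_cs}{complex minus solid state}
#' }
#' Capital-Delta values are in MHz (coupling-constant differences); small
#' delta values are dimensionless (eta differences). When all three contexts
#' share one single-molecule reference, `Delta_cs = Delta_c - Delta_s` and
#' `delta_cs = delta_c - delta_s` hold identically.
#'
#' @name quad-indices
NULL

as_context_entry <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "nqr_params") || is.list(x)) {
    if (is.null(x$cqcc) || is.null(x$eta)) {
      stop("context `", what, "` needs `cqcc` and `eta`", call. = FALSE)
    }
    return(nqr_params(x$cqcc[1L], x$eta[1L]))
  }
  if (is.numeric(x) && length(x) == 2L) return(nqr_params(x[1L], x[2L]))
  stop("context `", what, "` must be nqr_params or a (cqcc, eta) pair",
       call. = FALSE)
}

#' Bundle per-context NQR parameters for one nitrogen site
#'
#' @param site_label site name, e.g. `"-NH2"`.
#' @param single,solid,complex [nqr_params()] rows (or `c(cqcc, eta)` pairs)
#'   for the single-molecule, solid-state and protein-ligand-complex
#'   contexts; any may be omitted, but at least two must be present for any
#'   index to be computable.
#' @return A list of class `context_params`.
#' @export
context_params <- function(site_label, single = NULL, solid = NULL,
                           complex = NULL) {
  out <- list(site_label = as.character(site_label)[1L],
              single = as_context_entry(single, "single"),
              solid = as_context_entry(solid, "solid"),
              complex = as_context_entry(complex, "complex"))
  if (sum(!vapply(out[c("single", "solid", "complex")], is.null,
                  logical(1L))) < 2L) {
    stop("at least two contexts are required for site ", out$site_label,
         call. = FALSE)
  }
  structure(out, class = "context_params")
}

context_difference <- function(ctx, a, b) {
  for (w in c(a, b)) {
    if (is.null(ctx[[w]])) {
      stop("missing context `", w, "` for site ", ctx$site_label, call. = FALSE)
    }
  }
  c(delta = ctx[[a]]$cqcc - ctx[[b]]$cqcc,
    small_delta = ctx[[a]]$eta - ctx[[b]]$eta)
}

#' Solid-state effect indices (Delta_s, delta_s)
#'
#' `Delta_s = cqcc_solid - cqcc_single` (MHz) and
#' `delta_s = eta_solid - eta_single`.
#'
#' @param ctx a [context_params()] with `solid` and `single` present.
#' @return Named numeric vector `c(delta_s = , small_delta_s = )`.
#' @examples
#' ctx <- context_params("-NH2", single = c(3.758, 0.070),
#'                       solid = c(2.629, 0.750))
#' solid_state_indices(ctx) # -1.129, 0.68
#' @export
solid_state_indices <- function(ctx) {
  d <- context_difference(ctx, "solid", "single")
  c(delta_s = unname(d["delta"]), small_delta_s = unname(d["small_delta"]))
}

#' Complexation effect indices (Delta_c, delta_c)
#'
#' `Delta_c = cqcc_complex - cqcc_single` (MHz) and
#' `delta_c = eta_complex - eta_single`.
#'
#' @param ctx a [context_params()] with `complex` and `single` present.
#' @return Named numeric vector `c(delta_c = , small_delta_c = )`.
#' @export
complexation_indices <- function(ctx) {
  d <- context_difference(ctx, "complex", "single")
  c(delta_c = unname(d["delta"]), small_delta_c = unname(d["small_delta"]))
}

#' Solid-versus-complex indices (Delta_cs, delta_cs)
#'
#' `Delta_cs = cqcc_complex - cqcc_solid` (MHz) and
#' `delta_cs = eta_complex - eta_solid`. Small values mean the binding motif
#' realized in the crystal carries over to the protein pocket.
#'
#' @param ctx a [context_params()] with `complex` and `solid` present.
#' @return Named numeric vector `c(delta_cs = , small_delta_cs = )`.
#' @export
solid_vs_complex_indices <- function(ctx) {
  d <- context_difference(ctx, "complex", "solid")
  c(delta_cs = unname(d["delta"]), small_delta_cs = unname(d["small_delta"]))
}

#' Tabulate all computable quadrupolar indices for a set of sites
#'
#' One row per site; indices whose contexts are absent are reported as `NA`,
#' never as zero.
#'
#' @param records list of [context_params()].
#' @return Data frame with columns `site`, `delta_s`, `small_delta_s`,
#'   `delta_c`, `small_delta_c`, `delta_cs`, `small_delta_cs`.
#' @export
tabulate_indices <- function(records) {
  if (inherits(records, "context_params")) records <- list(records)
  if (!length(records)) stop("no context records supplied", call. = FALSE)
  labels <- vapply(records, function(r) r$site_label, character(1L))
  if (anyDuplicated(labels)) {
    stop("duplicate site labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  one <- function(ctx) {
    val <- function(fn, a, b) {
      if (is.null(ctx[[a]]) || is.null(ctx[[b]])) return(c(NA_real_, NA_real_))
      unname(fn(ctx))
    }
    s <- val(solid_state_indices, "solid", "single")
    cc <- val(complexation_indices, "complex", "single")
    cs <- val(solid_vs_complex_indices, "complex", "solid")
    data.frame(site = ctx$site_label,
               delta_s = s[1L], small_delta_s = s[2L],
               delta_c = cc[1L], small_delta_c = cc[2L],
               delta_cs = cs[1L], small_delta_cs = cs[2L],
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(records, one))
  rownames(out) <- NULL
  out
}
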