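#' NQR parameter algebra for spin-1 nuclei
#'
#' A single quadrupolar nitrogen (14N, spin I = 1) in zero field shows three
#' transition frequencies (nu_plus, nu_minus, nu_zero) fixed by two numbers:
#' the quadrupole coupling constant e2qQ/h (here `cqcc`, MHz, magnitude) and
#' the asymmetry parameter eta of the electric field gradient (EFG) tensor.
#' These helpers convert between the two representations and from a raw EFG
#' tensor.
#'
#' @name nqr-params
NULL

#' Construct an NQR parameter record
#'
#' @param cqcc quadrupole coupling constant magnitude |e2qQ/h| in MHz
#'   (non-negative).
#' @param eta asymmetry parameter, dimensionless in \[0, 1\].
#' @param site optional site label(s), e.g. `"-NH2"`.
#' @return A data frame of class `nqr_params` with columns `cqcc`, `eta` and,
#'   when given, `site`.
#' @examples
#' nqr_params(2.693, 0.475, site = "-NH2")
#' @export
nqr_params <- function(cqcc, eta, site = NULL) {
  cqcc <- as.numeric(cqcc)
  eta <- as.numeric(eta)
  if (length(cqcc) != length(eta)) {
    stop("`cqcc` and `eta` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(cqcc)) || any(!is.finite(eta))) {
    stop("NQR parameters must be finite", call. = FALSE)
  }
  if (any(cqcc < 0)) {
    stop("quadrupole coupling constant must be non-negative, got ",
         min(cqcc), call. = FALSE)
  }
  bad <- eta < 0 | eta > 1
  if (any(bad)) {
    stop("asymmetry parameter must lie in [0, 1], got ", eta[which(bad)[1L]],
         call. = FALSE)
  }
  out <- data.frame(cqcc = cqcc, eta = eta)
  if (!is.null(site)) out <- cbind(data.frame(site = as.character(site),
                                              stringsAsFactors = FALSE), out)
  class(out) <- c("nqr_params", class(out))
  out
}

#' NQR parameters from the two upper transition frequencies
#'
#' Inverts the spin-1 transition relations: `cqcc = (2/3)(nu_plus + nu_minus)`
#' and `eta = 3 (nu_plus - nu_minus) / (nu_plus + nu_minus)`. The lowest line
#' `nu_zero = nu_plus - nu_minus` carries no extra information and is not an
#' input.
#'
#' @param nu_plus,nu_minus transition frequencies in MHz; vectors are
#'   processed elementwise. Requires `nu_plus >= nu_minus > 0` (this bound
#'   guarantees `eta <= 1`).
#' @param site optional site label(s) forwarded to the result.
#' @return An [nqr_params()] data frame.
#' @examples
#' params_from_frequencies(2.340, 1.700) # cqcc 2.693, eta 0.475
#' @export
params_from_frequencies <- function(nu_plus, nu_minus, site = NULL) {
  nu_plus <- as.numeric(nu_plus)
  nu_minus <- as.numeric(nu_minus)
  if (length(nu_plus) != length(nu_minus)) {
    stop("`nu_plus` and `nu_minus` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(nu_plus)) || any(!is.finite(nu_minus))) {
    stop("frequencies must be finite numbers", call. = FALSE)
  }
  if (any(nu_minus <= 0)) {
    stop("frequencies must be positive, got nu_minus = ",
         min(nu_minus), call. = FALSE)
  }
  inv <- nu_plus < nu_minus
  if (any(inv)) {
    i <- which(inv)[1L]
    stop("nu_plus (", nu_plus[i], ") must not be smaller than nu_minus (",
         nu_minus[i], ")", call. = FALSE)
  }
  nqr_params(cqcc = (2 / 3) * (nu_plus + nu_minus),
             eta = 3 * (nu_plus - nu_minus) / (nu_plus + nu_minus),
             site = site)
}

#' Transition frequencies from NQR parameters
#'
#' For spin 1: `nu_plus = cqcc (3 + eta) / 4`, `nu_minus = cqcc (3 - eta) / 4`
#' and `nu_zero = nu_plus - nu_minus = cqcc eta / 2`. Exact inverse of
#' [params_from_frequencies()].
#'
#' @param params an [nqr_params()] object, or a numeric `cqcc` when `eta` is
#'   given separately.
#' @param eta asymmetry parameter(s) when `params` is numeric.
#' @return A data frame of class `frequency_triplet` with columns `nu_plus`,
#'   `nu_minus`, `nu_zero` (MHz) and any `site` column carried over.
#' @examples
#' frequencies_from_params(nqr_params(4.420, 0.602))
#' @export
frequencies_from_params <- function(params, eta = NULL) {
  if (is.numeric(params) && !is.null(eta)) params <- nqr_params(params, eta)
  if (!inherits(params, "nqr_params")) params <- nqr_params(params$cqcc, params$eta,
                                                            site = params$site)
  out <- data.frame(nu_plus = params$cqcc * (3 + params$eta) / 4,
                    nu_minus = params$cqcc * (3 - params$eta) / 4,
                    nu_zero = params$cqcc * params$eta / 2)
  if (!is.null(params$site)) out <- cbind(data.frame(site = params$site,
                                                     stringsAsFactors = FALSE), out)
  class(out) <- c("frequency_triplet", class(out))
  out
}

#' Conversion constant between EFG principal values and coupling constants
#'
#' `e2qQ/h` in frequency units equals `e * Q * q_zz / h`. With the quadrupole
#' moment Q in fm^2 and the EFG principal value q_zz in atomic units
#' (Eh / (e a0^2)), the product converts to MHz through CODATA-2018 constants:
#' about 2.3496 MHz per fm^2 per a.u.
#'
#' @return MHz per (fm^2 x atomic unit of EFG), a scalar.
#' @export
efg_conversion_mhz <- function() {
  hartree_j <- 4.3597447222071e-18  # Eh
  bohr_m <- 5.29177210903e-11       # a0
  planck_js <- 6.62607015e-34       # h
  # e cancels: (e * Q[m^2] * Eh/(e a0^2)) / h, Q given in fm^2 = 1e-30 m^2
  1e-30 * hartree_j / (bohr_m^2 * planck_js) * 1e-6
}

#' NQR parameters from an electric field gradient tensor
#'
#' Diagonalizes a symmetric (near-traceless) EFG tensor, orders the principal
#' values by magnitude `|q_xx| <= |q_yy| <= |q_zz|`, and returns
#' `eta = |q_xx - q_yy| / |q_zz|` together with
#' `cqcc = efg_conversion_mhz() * Q * |q_zz|`. Magnitude ordering (rather than
#' algebraic) is what keeps eta in \[0, 1\]; the signed principal values are
#' kept as attributes for anyone who needs the sign of q_zz.
#'
#' @param tensor 3x3 real symmetric matrix, atomic units.
#' @param quadrupole_moment nuclear quadrupole moment in fm^2; the default
#'   2.044 is the adopted 14N value.
#' @param sym_tol absolute tolerance for the symmetry check.
#' @return An [nqr_params()] row with attributes `principal_values` (signed,
#'   magnitude-ordered) and `q_zz` (signed largest principal value).
#' @examples
#' efg_to_params(diag(c(1, 1, -2)))
#' @export
efg_to_params <- function(tensor, quadrupole_moment = 2.044, sym_tol = 1e-8) {
  tensor <- as.matrix(tensor)
  if (!is.numeric(tensor) || !all(dim(tensor) == c(3L, 3L))) {
    stop("`tensor` must be a numeric 3x3 matrix", call. = FALSE)
  }
  if (max(abs(tensor - t(tensor))) > sym_tol) {
    stop("EFG tensor is not symmetric within tolerance ", sym_tol,
         call. = FALSE)
  }
  if (!is.numeric(quadrupole_moment) || quadrupole_moment <= 0) {
    stop("`quadrupole_moment` must be a positive area in fm^2", call. = FALSE)
  }
  ev <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[order(abs(ev))]        # |q_xx| <= |q_yy| <= |q_zz|
  q_zz <- ev[3L]
  if (abs(q_zz) < .Machine$double.eps^0.5) {
    stop("degenerate EFG tensor: largest principal value is zero, ",
         "eta is undefined", call. = FALSE)
  }
  eta <- abs(ev[1L] - ev[2L]) / abs(q_zz)
  eta <- min(max(eta, 0), 1)
  out <- nqr_params(cqcc = efg_conversion_mhz() * quadrupole_moment * abs(q_zz),
                    eta = eta)
  attr(out, "principal_values") <- ev
  attr(out, "q_zz") <- q_zz
  out
}
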