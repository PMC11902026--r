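#' Synthetic multi-site NQR spectrum generator
#'
#' Emulates the kind of zero-field 14N spectrum the assignment engine has to
#' untangle: several nitrogen sites, each contributing a consistent triplet,
#' plus Gaussian line-position noise and optional spurious lines (e.g.
#' molecular-motion satellites). Fully deterministic under `seed`.
#'
#' The defaults mirror the parameter ranges seen for amide/azine nitrogens
#' in nucleoside crystals: coupling constants 2.4-4.6 MHz, asymmetry
#' parameters 0.1-0.75.
#'
#' @param n_sites number of nitrogen sites.
#' @param cqcc_range coupling constant range in MHz (non-degenerate).
#' @param eta_range asymmetry parameter range within \[0, 1\].
#' @param noise_sd Gaussian noise SD added independently to each line (MHz).
#' @param n_spurious number of spurious lines drawn uniformly over the true
#'   line range.
#' @param seed integer seed fixing the whole output.
#' @return List with `lines` (shuffled numeric vector of
#'   `3 * n_sites + n_spurious` positions, MHz) and `truth` (data frame per
#'   site: `site`, `cqcc`, `eta`, noisy `nu_plus`, `nu_minus`, `nu_zero`).
#' @examples
#' spec <- generate_spectrum(n_sites = 4, noise_sd = 0, seed = 1)
#' length(spec$lines) # 12
#' @export
generate_spectrum <- function(n_sites = 4L, cqcc_range = c(2.4, 4.6),
                              eta_range = c(0.1, 0.75), noise_sd = 0.002,
                              n_spurious = 0L, seed = 1L) {
  if (n_sites < 1L) stop("`n_sites` must be positive", call. = FALSE)
  if (diff(cqcc_range) <= 0 || cqcc_range[1L] <= 0) {
    stop("`cqcc_range` must be a non-degenerate positive interval",
         call. = FALSE)
  }
  if (diff(eta_range) <= 0 || eta_range[1L] < 0 || eta_range[2L] > 1) {
    stop("`eta_range` must be a non-degenerate interval within [0, 1]",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (n_spurious < 0) stop("`n_spurious` must be non-negative", call. = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))

  cqcc <- stats::runif(n_sites, cqcc_range[1L], cqcc_range[2L])
  eta <- stats::runif(n_sites, eta_range[1L], eta_range[2L])
  fr <- frequencies_from_params(nqr_params(cqcc, eta))
  noisy <- as.matrix(fr[, c("nu_plus", "nu_minus", "nu_zero")]) +
    matrix(stats::rnorm(3L * n_sites, sd = noise_sd), ncol = 3L)
  truth <- data.frame(site = paste0("site", seq_len(n_sites)),
                      cqcc = cqcc, eta = eta,
                      nu_plus = noisy[, 1L], nu_minus = noisy[, 2L],
                      nu_zero = noisy[, 3L], stringsAsFactors = FALSE)
  lines <- as.vector(t(noisy))
  if (n_spurious > 0L) {
    lines <- c(lines, stats::runif(n_spurious, min(lines), max(lines)))
  }
  lines <- lines[sample.int(length(lines))]
  list(lines = lines, truth = truth)
}

#' Count ground-truth triplets recovered by a line grouping
#'
#' A site counts as recovered when one triplet of the partition matches its
#' three (noisy) line positions within `tol`.
#'
#' @param partition one element of a [group_lines()] result.
#' @param truth the `truth` data frame from [generate_spectrum()].
#' @param tol absolute matching tolerance in MHz.
#' @return Integer count of recovered sites.
#' @export
triplet_recovery <- function(partition, truth, tol = 1e-9) {
  tr <- partition$triplets
  hits <- 0L
  for (i in seq_len(nrow(truth))) {
    want <- sort(c(truth$nu_plus[i], truth$nu_minus[i], truth$nu_zero[i]),
                 decreasing = TRUE)
    for (k in seq_len(nrow(tr))) {
      got <- c(tr$nu_plus[k], tr$nu_minus[k], tr$nu_zero[k])
      if (all(abs(got - want) <= tol)) {
        hits <- hits + 1L
        break
      }
    }
  }
  hits
}
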