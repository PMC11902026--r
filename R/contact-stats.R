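#' Hirshfeld contact-surface statistics
#'
#' A crystal structure's Hirshfeld surface can be decomposed into percentage
#' contributions C_XY of contacts between element types X and Y. From these
#' the per-element surface fractions S_X, the random-contact expectation
#' R_XY, and the enrichment ratios E_XY = C_XY / R_XY follow. E_XY > 1 marks
#' a privileged contact, E_XY < 1 a disfavored one.
#'
#' @name contact-stats
NULL

#' Construct a contact-percentage matrix
#'
#' @param contact_pct symmetric numeric matrix of percentage contributions
#'   (element x element; upper/lower triangle may be given on either side,
#'   the constructor symmetrizes by summing mirrored off-diagonal entries
#'   when only one is filled).
#' @param elements element symbols (defaults to the matrix dimnames).
#' @param structure_id optional structure label.
#' @param closure_tol tolerance on the total percentage (default 1.5,
#'   accommodating per-cell rounding in published tables).
#' @return Object of class `contact_matrix`.
#' @export
contact_matrix <- function(contact_pct, elements = NULL, structure_id = NA,
                           closure_tol = 1.5) {
  m <- as.matrix(contact_pct)
  if (nrow(m) != ncol(m)) stop("contact matrix must be square", call. = FALSE)
  if (is.null(elements)) elements <- rownames(m)
  if (is.null(elements)) stop("element symbols required", call. = FALSE)
  m[is.na(m)] <- 0
  if (any(m < 0)) stop("contact percentages must be non-negative", call. = FALSE)
  # symmetrize: where only one triangle is filled, mirror it
  for (i in seq_len(nrow(m) - 1L)) {
    for (j in (i + 1L):ncol(m)) {
      if (m[i, j] == 0 && m[j, i] > 0) m[i, j] <- m[j, i]
      if (m[j, i] == 0 && m[i, j] > 0) m[j, i] <- m[i, j]
      if (abs(m[i, j] - m[j, i]) > 1e-9) {
        stop("contact matrix is not symmetric at ", elements[i], "/",
             elements[j], call. = FALSE)
      }
    }
  }
  dimnames(m) <- list(elements, elements)
  total <- sum(diag(m)) + sum(m[upper.tri(m)])
  if (abs(total - 100) > closure_tol) {
    stop("contact percentages sum to ", round(total, 2),
         ", not 100 within tolerance ", closure_tol, call. = FALSE)
  }
  structure(list(elements = elements, contact_pct = m,
                 structure_id = structure_id, total = total),
            class = "contact_matrix")
}

#' Per-element surface fractions from a contact matrix
#'
#' Each element's share of the molecular surface is its self-contact
#' percentage plus half of every mixed contact it participates in,
#' renormalized to sum to 100.
#'
#' @param cm a [contact_matrix()].
#' @return Named numeric vector of percentages summing to 100, class
#'   `surface_fractions`.
#' @export
surface_fractions <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  m <- cm$contact_pct
  if (!nrow(m)) stop("empty contact matrix", call. = FALSE)
  s <- diag(m) + 0.5 * (rowSums(m) - diag(m))
  s <- s / sum(s) * 100
  structure(s, class = "surface_fractions")
}

#' Expected random-contact percentages
#'
#' Under random mixing of surface patches, `R_XX = s_x^2 * 100` and
#' `R_XY = 2 s_x s_y * 100` for X != Y, with `s_x = S_X / 100`. The result
#' sums to 100 exactly (after normalizing the input fractions).
#'
#' @param sf a [surface_fractions()] vector (or named percentages summing to
#'   about 100).
#' @return Symmetric matrix of percentages whose upper triangle plus
#'   diagonal sums to 100.
#' @export
random_contacts <- function(sf) {
  s <- as.numeric(sf)
  names(s) <- names(sf)
  if (any(s < 0)) stop("negative surface fraction", call. = FALSE)
  if (abs(sum(s) - 100) > 1.5) {
    stop("surface fractions sum to ", round(sum(s), 2), ", expected 100",
         call. = FALSE)
  }
  p <- s / sum(s)
  r <- 2 * outer(p, p) * 100
  diag(r) <- p^2 * 100
  r
}

#' Enrichment ratios of a contact matrix
#'
#' `E_XY = C_XY / R_XY` over the element pairs of `cm`. Pairs whose random
#' expectation falls below `sparse_threshold` (percent) are flagged sparse:
#' their ratio is numerically unstable and they are excluded from downstream
#' summaries.
#'
#' @param cm a [contact_matrix()].
#' @param sparse_threshold minimum `R_XY` (percent) for a reliable ratio.
#' @return Data frame with one row per unordered element pair: `x`, `y`,
#'   `contact_pct`, `random_pct`, `enrichment`, `classification`
#'   (privileged / neutral / disfavored), `sparse`.
#' @export
enrichment <- function(cm, sparse_threshold = 0.5) {
  stopifnot(inherits(cm, "contact_matrix"))
  sf <- surface_fractions(cm)
  r <- random_contacts(sf)
  el <- cm$elements
  rows <- list()
  for (i in seq_along(el)) {
    for (j in i:length(el)) {
      cxy <- cm$contact_pct[i, j]
      rxy <- r[i, j]
      e <- if (rxy > 0) cxy / rxy else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        x = el[i], y = el[j], contact_pct = cxy, random_pct = rxy,
        enrichment = e,
        classification = if (is.na(e)) NA_character_
          else if (e > 1) "privileged" else if (e < 1) "disfavored" else "neutral",
        sparse = rxy < sparse_threshold,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_table", class(out))
  out
}

.align_channels <- function(a, b) {
  if ((is.null(names(a)) && length(a)) || (is.null(names(b)) && length(b))) {
    stop("contribution vectors must be named by contact channel", call. = FALSE)
  }
  channels <- union(names(a), names(b))
  if (!length(channels)) stop("both contribution vectors are empty", call. = FALSE)
  av <- ifelse(channels %in% names(a), a[channels], 0)
  bv <- ifelse(channels %in% names(b), b[channels], 0)
  av[is.na(av)] <- 0; bv[is.na(bv)] <- 0
  if (any(av < 0) || any(bv < 0)) {
    stop("contribution percentages must be non-negative", call. = FALSE)
  }
  list(a = av, b = bv, n = length(channels))
}

#' Root mean square deviation between contribution vectors
#'
#' Channels absent in one vector are zero-filled; the denominator is the
#' size of the channel union. A channel named in a vector but valued `NA`
#' (an empty table cell) still belongs to the union and counts as zero, so
#' the denominator reflects the declared channel layout.
#'
#' @param a,b named numeric vectors of percentage contributions (e.g.
#'   channels `N...C`, `N...H`, ...).
#' @return RMSD in percent.
#' @examples
#' f1 <- c("N...C" = 38.1, "N...H" = 60.3, "N...N" = 0, "N...O" = 1.6,
#'         "N...F" = 0)
#' f2 <- c("N...C" = 43.6, "N...H" = 51.5, "N...N" = 3.2, "N...O" = 1.8,
#'         "N...F" = 0)
#' contribution_rmsd(f1, f2) # 4.86
#' @export
contribution_rmsd <- function(a, b) {
  al <- .align_channels(a, b)
  sqrt(sum((al$a - al$b)^2) / al$n)
}

#' Euclidean distance between contribution vectors
#'
#' Same zero-fill convention as [contribution_rmsd()];
#' `ED = RMSD * sqrt(n)` holds by construction.
#'
#' @inheritParams contribution_rmsd
#' @return Euclidean distance in percent.
#' @export
contribution_euclidean <- function(a, b) {
  al <- .align_channels(a, b)
  sqrt(sum((al$a - al$b)^2))
}
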