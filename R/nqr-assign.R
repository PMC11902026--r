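#' Group a raw multi-line NQR spectrum into per-site triplets
#'
#' Each spin-1 nitrogen contributes three lines with the internal constraint
#' `nu_zero = nu_plus - nu_minus`, so a spectrum of 3n lines can be carved
#' into n site triplets by searching for partitions in which every triplet
#' (sorted descending as nu_plus >= nu_minus >= nu_zero) satisfies
#' `|nu_zero - (nu_plus - nu_minus)| <= tolerance`.
#'
#' With `allow_leftover = FALSE` (exhaustive mode) the line count must be a
#' multiple of three and full partitions are returned. With
#' `allow_leftover = TRUE` the search instead returns maximal sets of disjoint
#' consistent triplets, leaving spurious lines (e.g. molecular-motion
#' satellites) unassigned.
#'
#' @param frequencies numeric vector of line positions in MHz (>= 3 values).
#' @param tolerance consistency tolerance in MHz (default 0.01, the order of
#'   the resolution implied by three-decimal line positions).
#' @param allow_leftover logical; see Details.
#' @param max_results cap on the number of partitions returned.
#' @return Object of class `line_grouping`: a list of candidate partitions
#'   sorted by total consistency residual (ascending). Each partition is a
#'   list with `triplets` (data frame: `nu_plus`, `nu_minus`, `nu_zero`,
#'   `residual`), `leftover` (numeric vector of unassigned lines) and
#'   `total_residual`.
#' @examples
#' group_lines(c(3.0, 2.0, 1.0), tolerance = 0.01)
#' @export
group_lines <- function(frequencies, tolerance = 0.01,
                        allow_leftover = FALSE, max_results = 100L) {
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) < 3L) {
    stop("need at least 3 frequencies to form a triplet", call. = FALSE)
  }
  if (any(!is.finite(frequencies)) || any(frequencies < 0)) {
    stop("frequencies must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("`tolerance` must be positive", call. = FALSE)
  }
  n <- length(frequencies)
  if (!allow_leftover && n %% 3L != 0L) {
    stop("frequency count (", n, ") is not divisible by 3; use ",
         "`allow_leftover = TRUE` for spectra with spurious lines",
         call. = FALSE)
  }

  # candidate triplets: all index combinations whose sorted-descending lines
  # satisfy the nu_zero closure within tolerance
  combos <- utils::combn(n, 3L)
  cand <- list()
  for (k in seq_len(ncol(combos))) {
    idx <- combos[, k]
    v <- sort(frequencies[idx], decreasing = TRUE)
    res <- abs(v[3L] - (v[1L] - v[2L]))
    if (res <= tolerance) {
      cand[[length(cand) + 1L]] <- list(idx = idx, freq = v, residual = res)
    }
  }

  results <- list()
  # exact-cover style recursion: always branch on the smallest unused index,
  # either assigning it to a candidate triplet or (leftover mode) dropping it
  recurse <- function(unused, chosen, dropped) {
    if (length(results) >= max_results) return(invisible())
    if (length(unused) == 0L) {
      results[[length(results) + 1L]] <<- list(chosen = chosen,
                                               dropped = dropped)
      return(invisible())
    }
    pivot <- unused[1L]
    extended <- FALSE
    for (cc in cand) {
      if (pivot %in% cc$idx && all(cc$idx %in% unused)) {
        extended <- TRUE
        recurse(setdiff(unused, cc$idx), c(chosen, list(cc)), dropped)
      }
    }
    if (allow_leftover) {
      # drop the pivot line; maximality is enforced after collection
      recurse(unused[-1L], chosen, c(dropped, pivot))
    } else if (!extended) {
      return(invisible())
    }
    invisible()
  }
  recurse(seq_len(n), list(), integer())

  if (allow_leftover && length(results)) {
    sizes <- vapply(results, function(r) length(r$chosen), integer(1L))
    results <- results[sizes == max(sizes)]
    # dedupe identical triplet sets reached via different drop orders
    keys <- vapply(results, function(r) {
      paste(sort(vapply(r$chosen, function(cc) paste(sort(cc$idx), collapse = ","),
                        character(1L))), collapse = ";")
    }, character(1L))
    results <- results[!duplicated(keys)]
  }

  out <- lapply(results, function(r) {
    if (length(r$chosen)) {
      tr <- do.call(rbind, lapply(r$chosen, function(cc) {
        data.frame(nu_plus = cc$freq[1L], nu_minus = cc$freq[2L],
                   nu_zero = cc$freq[3L], residual = cc$residual)
      }))
      tr <- tr[order(-tr$nu_plus), , drop = FALSE]
      rownames(tr) <- NULL
    } else {
      tr <- data.frame(nu_plus = numeric(), nu_minus = numeric(),
                       nu_zero = numeric(), residual = numeric())
    }
    list(triplets = tr, leftover = frequencies[r$dropped],
         total_residual = sum(tr$residual))
  })
  out <- out[order(vapply(out, `[[`, numeric(1L), "total_residual"))]
  structure(out, class = "line_grouping", tolerance = tolerance)
}

#' @export
print.line_grouping <- function(x, ...) {
  cat(length(x), "candidate grouping(s), tolerance",
      attr(x, "tolerance"), "MHz\n")
  for (i in seq_along(x)) {
    cat("-- partition", i, "(total residual",
        format(x[[i]]$total_residual, digits = 3), "MHz)\n")
    print(x[[i]]$triplets, row.names = FALSE)
    if (length(x[[i]]$leftover)) {
      cat("   leftover lines:", paste(format(x[[i]]$leftover), collapse = ", "),
          "\n")
    }
  }
  invisible(x)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

#' Assign experimental NQR sites to calculated candidates
#'
#' Evaluates every bijection between n experimental and n calculated
#' parameter sets, scoring each by the Pearson correlation between the 3n
#' experimental and 3n calculated transition frequencies (regenerated via
#' [frequencies_from_params()]) together with the standard deviation of the
#' residuals about the identity line. Correlation is computed over
#' frequencies, not parameters, matching how calculated spectra are usually
#' validated against experiment. Ties on correlation are broken by the
#' smaller residual SD, then by lexicographic assignment order, so the result
#' is deterministic.
#'
#' @param experimental,calculated [nqr_params()] data frames with equal row
#'   counts (n >= 2; exhaustive search, intended for n <= 8). A `site` column
#'   on `calculated` labels the candidates.
#' @return Object of class `site_assignment`: list with `pairs` (integer
#'   vector, `pairs[i]` = calculated row assigned to experimental row i),
#'   `site` (labels in experimental order, when available), `pearson_r`, and
#'   `fit_sd` (MHz).
#' @examples
#' exp <- params_from_frequencies(c(2.34, 3.98), c(1.70, 2.65))
#' calc <- nqr_params(c(4.40, 2.70), c(0.60, 0.48), site = c("N(2)", "-NH2"))
#' assign_sites(exp, calc)
#' @export
assign_sites <- function(experimental, calculated) {
  if (nrow(experimental) != nrow(calculated)) {
    stop("experimental (", nrow(experimental), ") and calculated (",
         nrow(calculated), ") site counts differ", call. = FALSE)
  }
  n <- nrow(experimental)
  if (n < 2L) stop("need at least 2 sites (correlation undefined)", call. = FALSE)
  if (n > 8L) stop("exhaustive assignment supports at most 8 sites", call. = FALSE)

  fe <- frequencies_from_params(nqr_params(experimental$cqcc, experimental$eta))
  fc <- frequencies_from_params(nqr_params(calculated$cqcc, calculated$eta))
  em <- as.matrix(fe[, c("nu_plus", "nu_minus", "nu_zero")])
  cm <- as.matrix(fc[, c("nu_plus", "nu_minus", "nu_zero")])

  perms <- permutations_of(n)
  best <- NULL
  for (j in seq_len(nrow(perms))) {
    p <- perms[j, ]
    x <- as.vector(t(em))
    y <- as.vector(t(cm[p, , drop = FALSE]))
    r <- suppressWarnings(stats::cor(x, y))
    if (!is.finite(r)) r <- -Inf
    s <- stats::sd(y - x)
    if (is.null(best) || r > best$r + 1e-12 ||
        (abs(r - best$r) <= 1e-12 && s < best$s - 1e-12)) {
      best <- list(p = p, r = r, s = s)
    }
  }
  structure(list(pairs = best$p,
                 site = if (!is.null(calculated$site)) calculated$site[best$p],
                 pearson_r = best$r,
                 fit_sd = best$s),
            class = "site_assignment")
}

#' @export
print.site_assignment <- function(x, ...) {
  cat("site assignment (exhaustive):\n")
  lab <- if (!is.null(x$site)) x$site else paste0("calc#", x$pairs)
  for (i in seq_along(x$pairs)) {
    cat("  experimental", i, "->", lab[i], "\n")
  }
  cat("Pearson r =", format(x$pearson_r, digits = 6),
      " fit SD =", format(x$fit_sd, digits = 4), "MHz\n")
  invisible(x)
}
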