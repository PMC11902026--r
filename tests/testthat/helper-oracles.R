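# Independent brute-force oracles used to validate the search code.
# Deliberately written with different algorithms than the package internals.

# All ways to partition a vector's indices into unordered triplets.
all_triplet_partitions <- function(n) {
  if (n %% 3L != 0L) stop("n must be a multiple of 3")
  recurse <- function(idx) {
    if (!length(idx)) return(list(list()))
    first <- idx[1L]
    rest <- idx[-1L]
    out <- list()
    pairs <- utils::combn(rest, 2L)
    for (k in seq_len(ncol(pairs))) {
      tri <- c(first, pairs[, k])
      for (sub in recurse(setdiff(rest, pairs[, k]))) {
        out[[length(out) + 1L]] <- c(list(tri), sub)
      }
    }
    out
  }
  recurse(seq_len(n))
}

# Consistent-partition count by exhaustive enumeration.
count_consistent_partitions <- function(freqs, tol) {
  parts <- all_triplet_partitions(length(freqs))
  ok <- 0L
  good <- list()
  for (p in parts) {
    fine <- TRUE
    for (tri in p) {
      v <- sort(freqs[tri], decreasing = TRUE)
      if (abs(v[3L] - (v[1L] - v[2L])) > tol) {
        fine <- FALSE
        break
      }
    }
    if (fine) {
      ok <- ok + 1L
      good[[length(good) + 1L]] <- p
    }
  }
  list(count = ok, partitions = good)
}

# Recursive permutation enumeration (independent of the package's generator).
perms_oracle <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in perms_oracle(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# Best Pearson r over all bijections, scored exactly as the spec describes.
best_assignment_oracle <- function(experimental, calculated) {
  em <- as.matrix(frequencies_from_params(
    nqr_params(experimental$cqcc, experimental$eta)
  )[, c("nu_plus", "nu_minus", "nu_zero")])
  cm <- as.matrix(frequencies_from_params(
    nqr_params(calculated$cqcc, calculated$eta)
  )[, c("nu_plus", "nu_minus", "nu_zero")])
  best_r <- -Inf
  best_p <- NULL
  for (p in perms_oracle(nrow(em))) {
    r <- stats::cor(as.vector(t(em)), as.vector(t(cm[p, , drop = FALSE])))
    if (is.finite(r) && r > best_r) {
      best_r <- r
      best_p <- p
    }
  }
  list(pairs = best_p, pearson_r = best_r)
}

# --- maximum common connected edge subgraph, brute force ---------------------

.oracle_atom_label <- function(g) paste0(g$elements, ifelse(g$aromatic, ":ar", ""))
.oracle_bond_label <- function(g) ifelse(g$bonds$aromatic, "ar",
                                         as.character(g$bonds$order))

# Is the chosen edge set of gA (assumed connected) embeddable in gB with
# matching atom/bond labels? Backtracking over atom images.
.embeddable <- function(gA, edges, gB) {
  la <- .oracle_atom_label(gA); lb <- .oracle_atom_label(gB)
  bla <- .oracle_bond_label(gA); blb <- .oracle_bond_label(gB)
  ea <- gA$bonds[edges, , drop = FALSE]
  eal <- bla[edges]
  atoms <- unique(c(ea$a, ea$b))
  nB <- length(gB$elements)
  bmat <- matrix(NA_character_, nB, nB)
  for (k in seq_len(nrow(gB$bonds))) {
    bmat[gB$bonds$a[k], gB$bonds$b[k]] <- blb[k]
    bmat[gB$bonds$b[k], gB$bonds$a[k]] <- blb[k]
  }
  assign_atom <- function(pos, mapping) {
    if (pos > length(atoms)) return(TRUE)
    at <- atoms[pos]
    for (cand in seq_len(nB)) {
      if (cand %in% mapping) next
      if (lb[cand] != la[at]) next
      mapping[as.character(at)] <- cand
      ok <- TRUE
      for (k in seq_len(nrow(ea))) {
        ia <- mapping[as.character(ea$a[k])]
        ib <- mapping[as.character(ea$b[k])]
        if (is.na(ia) || is.na(ib)) next
        if (is.na(bmat[ia, ib]) || bmat[ia, ib] != eal[k]) {
          ok <- FALSE
          break
        }
      }
      if (ok && assign_atom(pos + 1L, mapping)) return(TRUE)
      mapping <- mapping[names(mapping) != as.character(at)]
    }
    FALSE
  }
  assign_atom(1L, stats::setNames(integer(), character()))
}

.edges_connected <- function(g, edges) {
  if (length(edges) <= 1L) return(TRUE)
  e <- g$bonds[edges, , drop = FALSE]
  ig <- igraph::graph_from_edgelist(cbind(as.character(e$a),
                                          as.character(e$b)),
                                    directed = FALSE)
  igraph::is_connected(ig)
}

mces_oracle <- function(gA, gB) {
  mA <- nrow(gA$bonds)
  if (mA == 0L || nrow(gB$bonds) == 0L) return(0L)
  best <- 0L
  for (size in seq(mA, 1L)) {
    if (size <= best) break
    sets <- utils::combn(mA, size, simplify = FALSE)
    for (s in sets) {
      if (!.edges_connected(gA, s)) next
      if (.embeddable(gA, s, gB)) {
        best <- size
        break
      }
    }
    if (best == size) break
  }
  best
}

# Random small labeled molecular graph (connected), for property tests.
random_toy_graph <- function(n_atoms, extra_edges = 1L) {
  elements <- sample(c("C", "N", "O"), n_atoms, replace = TRUE)
  bonds <- data.frame(a = integer(), b = integer(), order = numeric(),
                      aromatic = logical())
  for (i in seq_len(n_atoms)[-1L]) {
    bonds <- rbind(bonds, data.frame(a = sample.int(i - 1L, 1L), b = i,
                                     order = sample(c(1, 2), 1L),
                                     aromatic = FALSE))
  }
  tries <- 0L
  while (extra_edges > 0L && tries < 20L) {
    tries <- tries + 1L
    ij <- sort(sample.int(n_atoms, 2L))
    if (any(bonds$a == ij[1L] & bonds$b == ij[2L])) next
    bonds <- rbind(bonds, data.frame(a = ij[1L], b = ij[2L],
                                     order = sample(c(1, 2), 1L),
                                     aromatic = FALSE))
    extra_edges <- extra_edges - 1L
  }
  molecular_graph(elements, bonds)
}
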