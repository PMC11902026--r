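#' Molecular similarity kernels
#'
#' Three ligand-vs-reference similarity measures over 2D structures, all
#' symmetric with range \[0, 1\] and self-similarity 1:
#' \itemize{
#'   \item fingerprint Tanimoto over path-based hashed fingerprints,
#'   \item atom-pair Tanimoto over (descriptor, descriptor, topological
#'     distance) multisets,
#'   \item maximum common substructure (connected maximal common edge
#'     subgraph) similarity.
#' }
#' Hydrogens are implicit throughout; comparisons act on heavy-atom graphs.
#'
#' @name molsim
NULL

#' Construct a molecular graph
#'
#' Low-level constructor (used by [parse_structure()] and handy for toy
#' graphs in examples/tests). Bonds are undirected; at most one bond per
#' atom pair, no self-bonds.
#'
#' @param elements character vector of element symbols (heavy atoms).
#' @param bonds data frame with integer columns `a`, `b` (atom indices),
#'   numeric `order` (1, 2, 3) and logical `aromatic`.
#' @param aromatic logical per-atom aromatic flags (default all `FALSE`).
#' @param charge integer formal charges (default 0).
#' @param provenance source text, e.g. the SMILES string.
#' @return An object of class `molecular_graph`.
#' @export
molecular_graph <- function(elements, bonds = NULL, aromatic = NULL,
                            charge = NULL, provenance = NA_character_) {
  elements <- as.character(elements)
  n <- length(elements)
  if (n == 0L) stop("molecular graph needs at least one atom", call. = FALSE)
  if (is.null(aromatic)) aromatic <- rep(FALSE, n)
  if (is.null(charge)) charge <- rep(0L, n)
  if (is.null(bonds)) {
    bonds <- data.frame(a = integer(), b = integer(), order = numeric(),
                        aromatic = logical())
  }
  bonds <- as.data.frame(bonds)
  if (!all(c("a", "b", "order") %in% names(bonds))) {
    stop("`bonds` needs columns a, b, order", call. = FALSE)
  }
  if (is.null(bonds$aromatic)) bonds$aromatic <- rep(FALSE, nrow(bonds))
  if (nrow(bonds)) {
    if (any(bonds$a < 1L | bonds$a > n | bonds$b < 1L | bonds$b > n)) {
      stop("bond endpoint out of range", call. = FALSE)
    }
    if (any(bonds$a == bonds$b)) stop("self-bonds are not allowed", call. = FALSE)
    key <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
    if (anyDuplicated(key)) stop("duplicate bond between one atom pair",
                                 call. = FALSE)
  }
  structure(list(elements = elements, aromatic = as.logical(aromatic),
                 charge = as.integer(charge), bonds = bonds,
                 hydrogens = "implicit", provenance = provenance),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("molecular graph:", length(x$elements), "heavy atoms,",
      nrow(x$bonds), "bonds",
      if (any(x$aromatic)) sprintf("(%d aromatic atoms)", sum(x$aromatic)),
      "\n")
  if (!is.na(x$provenance)) cat("  from:", x$provenance, "\n")
  invisible(x)
}

# MDL V2000 old-style charge codes (column kept by ChemmineR's atom block)
.mdl_charge <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
           `6` = -2L, `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  unname(out)
}

#' Parse a SMILES string into a molecular graph
#'
#' Parsing and 2D perception are delegated to OpenBabel (through
#' ChemmineR/ChemmineOB); aromaticity is then perceived per ring with
#' [ChemmineR::rings()], and atoms/bonds of aromatic rings are flagged.
#'
#' @param smiles a single SMILES string.
#' @param id optional molecule identifier stored as the graph name.
#' @return A [molecular_graph()].
#' @examples
#' \donttest{
#' parse_structure("c1cc[nH]c1")  # pyrrole: 5 aromatic atoms
#' }
#' @export
parse_structure <- function(smiles, id = NULL) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("`smiles` must be a single non-empty string", call. = FALSE)
  }
  names(smiles) <- if (is.null(id)) "mol" else id
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) {
      stop("SMILES parse error in \"", smiles, "\": ", conditionMessage(e),
           call. = FALSE)
    })
  sdf <- sdf[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  if (nrow(ab) == 0L) {
    stop("SMILES parse error in \"", smiles, "\": no atoms produced",
         call. = FALSE)
  }
  elements <- sub("_.*$", "", rownames(ab))
  charge <- if ("C5" %in% colnames(ab)) .mdl_charge(ab[, "C5"]) else
    rep(0L, nrow(ab))
  bb <- ChemmineR::bondblock(sdf)
  bonds <- if (is.null(bb) || length(bb) == 0L || is.null(dim(bb)) ||
               nrow(bb) == 0L || ncol(bb) < 3L) {
    data.frame(a = integer(), b = integer(), order = numeric(),
               aromatic = logical())
  } else {
    data.frame(a = as.integer(bb[, 1L]), b = as.integer(bb[, 2L]),
               order = as.numeric(bb[, 3L]), aromatic = FALSE)
  }

  aromatic <- rep(FALSE, length(elements))
  if (nrow(bonds)) {
    rng <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                    error = function(e) NULL)
    if (!is.null(rng) && length(rng$RINGS)) {
      for (k in seq_along(rng$RINGS)) {
        if (!isTRUE(rng$AROMATIC[[k]])) next
        ring_idx <- as.integer(sub("^.*_", "", rng$RINGS[[k]]))
        aromatic[ring_idx] <- TRUE
        in_ring <- bonds$a %in% ring_idx & bonds$b %in% ring_idx
        bonds$aromatic[in_ring] <- TRUE
      }
    }
  }
  molecular_graph(elements, bonds, aromatic = aromatic, charge = charge,
                  provenance = unname(smiles))
}

.atom_label <- function(g) {
  paste0(g$elements, ifelse(g$aromatic, ":ar", ""))
}

.bond_label <- function(g) {
  ifelse(g$bonds$aromatic, "ar", as.character(g$bonds$order))
}

.adjacency_list <- function(g) {
  n <- length(g$elements)
  adj <- vector("list", n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[k]; b <- g$bonds$b[k]
      adj[[a]] <- rbind(adj[[a]], c(b, k))
      adj[[b]] <- rbind(adj[[b]], c(a, k))
    }
  }
  adj
}

# deterministic 32-bit-safe polynomial string hash
.hash_string <- function(s, nbits) {
  codes <- utf8ToInt(s)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  as.integer(h %% nbits) + 1L
}

#' Path-based hashed fingerprint
#'
#' Enumerates all simple labeled paths of 0 to `max_path` bonds (atom labels
#' are element plus aromatic flag, bond labels order/aromatic), canonicalizes
#' each path string against its reversal, and hashes the distinct strings
#' onto a fixed-length bit set.
#'
#' @param g a [molecular_graph()].
#' @param nbits fingerprint length in bits (default 2048).
#' @param max_path maximum path length in bonds (default 7).
#' @return Object of class `fingerprint`: list with `bits` (sorted set bit
#'   positions), `nbits`, `max_path`, `scheme`.
#' @export
path_fingerprint <- function(g, nbits = 2048L, max_path = 7L) {
  stopifnot(inherits(g, "molecular_graph"))
  al <- .atom_label(g)
  bl <- .bond_label(g)
  adj <- .adjacency_list(g)
  paths <- new.env(parent = emptyenv())
  add_path <- function(str) assign(str, TRUE, envir = paths)

  walk <- function(atom, visited, str, depth) {
    rstr <- .reverse_path(str)
    add_path(if (str <= rstr) str else rstr)
    if (depth >= max_path) return(invisible())
    nb <- adj[[atom]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1L]
      if (visited[nxt]) next
      visited[nxt] <- TRUE
      walk(nxt, visited, paste0(str, "|", bl[nb[r, 2L]], "|", al[nxt]),
           depth + 1L)
      visited[nxt] <- FALSE
    }
    invisible()
  }
  for (start in seq_along(al)) {
    visited <- rep(FALSE, length(al))
    visited[start] <- TRUE
    walk(start, visited, al[start], 0L)
  }
  strs <- ls(paths)
  bits <- sort(unique(vapply(strs, .hash_string, integer(1L), nbits = nbits)))
  structure(list(bits = bits, nbits = as.integer(nbits),
                 max_path = as.integer(max_path), scheme = "path/poly131"),
            class = "fingerprint")
}

.reverse_path <- function(str) {
  parts <- strsplit(str, "|", fixed = TRUE)[[1L]]
  paste(rev(parts), collapse = "|")
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|` over set bits; defined as 1 when both
#' fingerprints are empty (two structureless inputs are indistinguishable).
#'
#' @param fp_a,fp_b [path_fingerprint()] objects with identical parameters.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(fp_a, fp_b) {
  stopifnot(inherits(fp_a, "fingerprint"), inherits(fp_b, "fingerprint"))
  if (fp_a$nbits != fp_b$nbits || fp_a$max_path != fp_b$max_path ||
      fp_a$scheme != fp_b$scheme) {
    stop("fingerprint parameters differ; recompute with a common scheme",
         call. = FALSE)
  }
  u <- length(union(fp_a$bits, fp_b$bits))
  if (u == 0L) return(1)
  length(intersect(fp_a$bits, fp_b$bits)) / u
}

#' Atom-pair multiset of a molecular graph
#'
#' Each heavy-atom pair (i < j) at finite topological distance d >= 1
#' contributes one count to the key (descriptor_i, descriptor_j, d), with
#' descriptors (element, heavy-neighbor count, aromatic flag) stored in
#' canonical order.
#'
#' @param g a [molecular_graph()].
#' @return Object of class `atom_pair_multiset`: named integer vector of
#'   counts with attribute `scheme`.
#' @export
atom_pairs <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  n <- length(g$elements)
  deg <- rep(0L, n)
  if (nrow(g$bonds)) {
    tab <- table(factor(c(g$bonds$a, g$bonds$b), levels = seq_len(n)))
    deg <- as.integer(tab)
  }
  desc <- paste0(g$elements, "(", deg, ifelse(g$aromatic, ",ar", ""), ")")
  counts <- integer()
  if (n >= 2L && nrow(g$bonds)) {
    ig <- igraph::graph_from_edgelist(as.matrix(g$bonds[, c("a", "b")]),
                                      directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0L, n - igraph::vcount(ig)))
    d <- igraph::distances(ig)
    keys <- character()
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dij <- d[i, j]
        if (!is.finite(dij) || dij < 1) next
        pair <- sort(c(desc[i], desc[j]))
        keys <- c(keys, paste(pair[1L], pair[2L], dij, sep = "|"))
      }
    }
    if (length(keys)) {
      tb <- table(keys)
      counts <- as.integer(tb)
      names(counts) <- names(tb)
    }
  }
  structure(counts, class = "atom_pair_multiset",
            scheme = "element+degree+aromatic")
}

#' Tanimoto similarity between atom-pair multisets
#'
#' `sum(min(count_a, count_b)) / sum(max(count_a, count_b))` over the union
#' of keys; 1 when both multisets are empty.
#'
#' @param a,b [atom_pairs()] multisets built with the same descriptor scheme.
#' @return Similarity in \[0, 1\].
#' @export
atom_pair_tanimoto <- function(a, b) {
  stopifnot(inherits(a, "atom_pair_multiset"), inherits(b, "atom_pair_multiset"))
  if (!identical(attr(a, "scheme"), attr(b, "scheme"))) {
    stop("atom-pair descriptor schemes differ", call. = FALSE)
  }
  keys <- union(names(a), names(b))
  if (!length(keys)) return(1)
  ca <- ifelse(keys %in% names(a), unclass(a)[keys], 0L)
  cb <- ifelse(keys %in% names(b), unclass(b)[keys], 0L)
  ca[is.na(ca)] <- 0L; cb[is.na(cb)] <- 0L
  sum(pmin(ca, cb)) / sum(pmax(ca, cb))
}

# --- maximum common (connected) edge subgraph -------------------------------

.edge_table <- function(g) {
  if (!nrow(g$bonds)) {
    return(data.frame(a = integer(), b = integer(), label = character()))
  }
  data.frame(a = g$bonds$a, b = g$bonds$b, label = .bond_label(g),
             stringsAsFactors = FALSE)
}

#' Maximum common substructure similarity
#'
#' Finds the connected maximal common edge subgraph of two molecular graphs,
#' matching atoms on element + aromatic flag and bonds on order/aromatic
#' label, and returns `m / (e_a + e_b - m)` where `m` is the common edge
#' count and `e_a`, `e_b` the graphs' edge counts. The search is an exact
#' branch-and-bound (complete for typical drug-sized molecules); if it
#' exceeds `time_limit` seconds it falls back to a seeded randomized
#' multi-start growth and the result is flagged `exact = FALSE` in its
#' attributes.
#'
#' Both graphs edgeless gives similarity 1 (single atoms carry no edge
#' structure to distinguish); exactly one edgeless gives 0.
#'
#' @param g_a,g_b [molecular_graph()] objects (non-empty).
#' @param time_limit budget for the exact search, seconds.
#' @param restarts number of randomized restarts in the fallback.
#' @param seed seed for the fallback search.
#' @return Similarity in \[0, 1\] with attributes `edges` (matched edge
#'   count) and `exact` (logical).
#' @export
mcs_similarity <- function(g_a, g_b, time_limit = 10, restarts = 500L,
                           seed = 1L) {
  stopifnot(inherits(g_a, "molecular_graph"), inherits(g_b, "molecular_graph"))
  if (!length(g_a$elements) || !length(g_b$elements)) {
    stop("both molecular graphs must be non-empty", call. = FALSE)
  }
  ea <- nrow(g_a$bonds); eb <- nrow(g_b$bonds)
  if (ea == 0L && eb == 0L) {
    return(structure(1, edges = 0L, exact = TRUE))
  }
  if (ea == 0L || eb == 0L) {
    return(structure(0, edges = 0L, exact = TRUE))
  }
  res <- .mces_search(g_a, g_b, time_limit = time_limit,
                      restarts = restarts, seed = seed)
  m <- res$size
  structure(m / (ea + eb - m), edges = m, exact = res$exact)
}

# Branch-and-bound over connected common edge subgraphs. Completeness:
# solutions are enumerated by their smallest A-edge index (the seed); within
# a seed, the recursion branches on the first extendable A-edge, either
# mapping it to a compatible B-edge or excluding it for the branch.
.mces_search <- function(g_a, g_b, time_limit, restarts, seed) {
  la <- .atom_label(g_a); lb <- .atom_label(g_b)
  eta <- .edge_table(g_a); etb <- .edge_table(g_b)
  mA <- nrow(eta); mB <- nrow(etb)
  nA <- length(la); nB <- length(lb)

  # compat[[i]]: B-edge indices compatible with A-edge i in some orientation
  compat <- vector("list", mA)
  for (i in seq_len(mA)) {
    ok <- etb$label == eta$label[i] &
      ((lb[etb$a] == la[eta$a[i]] & lb[etb$b] == la[eta$b[i]]) |
         (lb[etb$a] == la[eta$b[i]] & lb[etb$b] == la[eta$a[i]]))
    compat[[i]] <- which(ok)
  }

  # A-edges incident to each A-atom
  incA <- vector("list", nA)
  for (i in seq_len(mA)) {
    incA[[eta$a[i]]] <- c(incA[[eta$a[i]]], i)
    incA[[eta$b[i]]] <- c(incA[[eta$b[i]]], i)
  }

  env <- new.env(parent = emptyenv())
  env$best <- 0L
  env$nodes <- 0L
  env$deadline <- Sys.time() + time_limit
  env$timed_out <- FALSE
  env$mapA <- rep(0L, nA)   # A-atom -> B-atom
  env$mapB <- rep(0L, nB)   # B-atom -> A-atom (for injectivity)
  env$usedB <- rep(FALSE, mB)

  try_orientations <- function(i, j) {
    # returns list of atom-pair assignments (Aatom, Batom) x2 or NULL per
    # orientation; caller applies/undoes
    ors <- list(cbind(c(eta$a[i], eta$b[i]), c(etb$a[j], etb$b[j])),
                cbind(c(eta$a[i], eta$b[i]), c(etb$b[j], etb$a[j])))
    keep <- logical(2L)
    for (k in 1:2) {
      o <- ors[[k]]
      ok <- TRUE
      for (r in 1:2) {
        ai <- o[r, 1L]; bi <- o[r, 2L]
        if (la[ai] != lb[bi]) { ok <- FALSE; break }
        ma <- env$mapA[ai]; mb <- env$mapB[bi]
        if ((ma != 0L && ma != bi) || (mb != 0L && mb != ai)) { ok <- FALSE; break }
      }
      keep[k] <- ok
    }
    ors[keep]
  }

  recurse <- function(matched, excluded) {
    env$nodes <- env$nodes + 1L
    if (env$nodes %% 512L == 0L && Sys.time() > env$deadline) {
      env$timed_out <- TRUE
    }
    if (env$timed_out) return(invisible())
    n_matched <- sum(matched)
    # frontier: unmatched, unexcluded A-edges touching a mapped atom
    frontier <- integer()
    for (v in which(env$mapA != 0L)) {
      for (e in incA[[v]]) {
        if (!matched[e] && !excluded[e]) frontier <- c(frontier, e)
      }
    }
    frontier <- unique(frontier)
    if (!length(frontier)) {
      if (n_matched > env$best) env$best <- n_matched
      return(invisible())
    }
    # bound
    ub <- n_matched + min(length(which(!matched & !excluded)),
                          sum(!env$usedB))
    if (ub <= env$best) return(invisible())
    e <- frontier[1L]
    for (j in compat[[e]]) {
      if (env$usedB[j]) next
      for (o in try_orientations(e, j)) {
        newly <- o[env$mapA[o[, 1L]] == 0L, , drop = FALSE]
        env$mapA[newly[, 1L]] <- newly[, 2L]
        env$mapB[newly[, 2L]] <- newly[, 1L]
        env$usedB[j] <- TRUE
        matched[e] <- TRUE
        recurse(matched, excluded)
        matched[e] <- FALSE
        env$usedB[j] <- FALSE
        env$mapA[newly[, 1L]] <- 0L
        env$mapB[newly[, 2L]] <- 0L
      }
    }
    excluded[e] <- TRUE
    recurse(matched, excluded)
    invisible()
  }

  for (s in seq_len(mA)) {
    if (env$timed_out) break
    if (mA - s + 1L <= env$best) break  # cannot beat best with edges >= s
    excluded0 <- rep(FALSE, mA)
    if (s > 1L) excluded0[seq_len(s - 1L)] <- TRUE
    for (j in compat[[s]]) {
      if (env$timed_out) break
      for (o in try_orientations(s, j)) {
        env$mapA[o[, 1L]] <- o[, 2L]
        env$mapB[o[, 2L]] <- o[, 1L]
        env$usedB[j] <- TRUE
        matched <- rep(FALSE, mA); matched[s] <- TRUE
        recurse(matched, excluded0)
        env$usedB[j] <- FALSE
        env$mapA[o[, 1L]] <- 0L
        env$mapB[o[, 2L]] <- 0L
      }
    }
  }

  if (!env$timed_out) {
    return(list(size = env$best, exact = TRUE))
  }

  # randomized fallback: seeded multi-start greedy growth, keep the largest
  best_rand <- env$best
  rng <- .seeded_rng(seed)
  for (r in seq_len(restarts)) {
    sz <- .mces_random_growth(eta, etb, la, lb, compat, incA, nA, nB, rng)
    if (sz > best_rand) best_rand <- sz
  }
  list(size = best_rand, exact = FALSE)
}

.seeded_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- as.numeric(seed) %% 2147483647
  if (env$state <= 0) env$state <- env$state + 2147483646
  function(n) {  # Lehmer generator: pick from 1..n
    env$state <- (env$state * 16807) %% 2147483647
    as.integer(env$state %% n) + 1L
  }
}

.mces_random_growth <- function(eta, etb, la, lb, compat, incA, nA, nB, rng) {
  mA <- nrow(eta); mB <- nrow(etb)
  mapA <- rep(0L, nA); mapB <- rep(0L, nB)
  usedB <- rep(FALSE, mB); matched <- rep(FALSE, mA)
  s <- rng(mA)
  if (!length(compat[[s]])) return(0L)
  j <- compat[[s]][rng(length(compat[[s]]))]
  orient <- rng(2L)
  apair <- c(eta$a[s], eta$b[s])
  bpair <- if (orient == 1L) c(etb$a[j], etb$b[j]) else c(etb$b[j], etb$a[j])
  if (la[apair[1L]] != lb[bpair[1L]] || la[apair[2L]] != lb[bpair[2L]]) {
    bpair <- rev(bpair)
    if (la[apair[1L]] != lb[bpair[1L]] || la[apair[2L]] != lb[bpair[2L]]) {
      return(0L)
    }
  }
  mapA[apair] <- bpair; mapB[bpair] <- apair
  usedB[j] <- TRUE; matched[s] <- TRUE
  repeat {
    frontier <- unique(unlist(lapply(which(mapA != 0L), function(v) incA[[v]])))
    frontier <- frontier[!matched[frontier]]
    extended <- FALSE
    if (length(frontier)) {
      # Fisher-Yates with the local generator (keeps the fallback seeded)
      for (k in rev(seq_along(frontier))[-length(frontier)]) {
        swap <- rng(k)
        tmp <- frontier[k]; frontier[k] <- frontier[swap]; frontier[swap] <- tmp
      }
      for (e in frontier) {
        cands <- compat[[e]][!usedB[compat[[e]]]]
        ok_j <- 0L; ok_bp <- NULL
        for (j2 in cands) {
          for (bp in list(c(etb$a[j2], etb$b[j2]), c(etb$b[j2], etb$a[j2]))) {
            ap <- c(eta$a[e], eta$b[e])
            fine <- TRUE
            for (r in 1:2) {
              if (la[ap[r]] != lb[bp[r]]) { fine <- FALSE; break }
              if ((mapA[ap[r]] != 0L && mapA[ap[r]] != bp[r]) ||
                  (mapB[bp[r]] != 0L && mapB[bp[r]] != ap[r])) {
                fine <- FALSE; break
              }
            }
            if (fine) { ok_j <- j2; ok_bp <- rbind(ap, bp); break }
          }
          if (ok_j) break
        }
        if (ok_j) {
          ap <- ok_bp[1L, ]; bp <- ok_bp[2L, ]
          mapA[ap] <- bp; mapB[bp] <- ap
          usedB[ok_j] <- TRUE; matched[e] <- TRUE
          extended <- TRUE
          break
        }
      }
    }
    if (!extended) break
  }
  sum(matched)
}

#' Similarity of a panel of SMILES against a reference
#'
#' @param smiles named character vector of SMILES (names are ligand ids).
#' @param reference id of the reference ligand (must be in `names(smiles)`).
#' @param kernels subset of `c("tanimoto", "atom_pair", "mcs")`.
#' @param ... forwarded to [mcs_similarity()].
#' @return Data frame usable as [similarity_scores()] rows.
#' @export
similarity_panel <- function(smiles, reference,
                             kernels = c("tanimoto", "atom_pair", "mcs"),
                             ...) {
  kernels <- match.arg(kernels, several.ok = TRUE)
  if (is.null(names(smiles)) || !reference %in% names(smiles)) {
    stop("`smiles` must be named and include the reference id", call. = FALSE)
  }
  graphs <- lapply(seq_along(smiles),
                   function(i) parse_structure(smiles[[i]], names(smiles)[i]))
  names(graphs) <- names(smiles)
  gref <- graphs[[reference]]
  fpref <- if ("tanimoto" %in% kernels) path_fingerprint(gref)
  apref <- if ("atom_pair" %in% kernels) atom_pairs(gref)
  rows <- lapply(names(graphs), function(id) {
    g <- graphs[[id]]
    data.frame(
      ligand_id = id,
      tanimoto = if ("tanimoto" %in% kernels)
        tanimoto(fpref, path_fingerprint(g)) else NA_real_,
      atom_pair = if ("atom_pair" %in% kernels)
        atom_pair_tanimoto(apref, atom_pairs(g)) else NA_real_,
      mcs = if ("mcs" %in% kernels)
        as.numeric(mcs_similarity(gref, g, ...)) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
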