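test_that("SMILES parsing yields the expected heavy-atom graphs", {
  m <- parse_structure("C")
  expect_length(m$elements, 1L)
  expect_equal(nrow(m$bonds), 0L)

  # aromatic 1,2,4-triazole ring
  tz <- parse_structure("c1nc[nH]n1")
  expect_length(tz$elements, 5L)
  expect_equal(nrow(tz$bonds), 5L)
  expect_true(all(tz$aromatic))
  expect_true(all(tz$bonds$aromatic))

  # ribavirin: C8H12N4O5 -> 17 heavy atoms
  rbv <- parse_structure(ligand_smiles()[["RBV"]])
  expect_length(rbv$elements, 17L)
  expect_equal(sum(rbv$elements == "N"), 4L)
  expect_equal(sum(rbv$elements == "O"), 5L)

  expect_error(parse_structure("C1CC"), "parse error")
  expect_error(parse_structure(""), "non-empty")
})

test_that("molecular graph invariants are enforced", {
  expect_error(molecular_graph(character()), "at least one atom")
  expect_error(molecular_graph("C", data.frame(a = 1L, b = 1L, order = 1)),
               "self-bonds")
  expect_error(molecular_graph(c("C", "C"),
                               data.frame(a = c(1L, 2L), b = c(2L, 1L),
                                          order = c(1, 1))),
               "duplicate bond")
  expect_error(molecular_graph(c("C", "C"),
                               data.frame(a = 1L, b = 3L, order = 1)),
               "out of range")
})

test_that("fingerprint Tanimoto follows the set definition", {
  fp <- function(bits) structure(list(bits = bits, nbits = 2048L,
                                      max_path = 7L, scheme = "path/poly131"),
                                 class = "fingerprint")
  expect_equal(tanimoto(fp(c(1L, 2L, 3L)), fp(c(2L, 3L, 4L))), 0.5)
  expect_equal(tanimoto(fp(1:5), fp(1:5)), 1)
  expect_equal(tanimoto(fp(1:3), fp(4:6)), 0)
  expect_equal(tanimoto(fp(integer()), fp(integer())), 1)
  other <- fp(1:3); other$nbits <- 1024L
  expect_error(tanimoto(fp(1:3), other), "parameters differ")

  g <- parse_structure("CCO")
  expect_equal(tanimoto(path_fingerprint(g), path_fingerprint(g)), 1)
})

test_that("atom-pair Tanimoto follows the multiset definition", {
  ms <- function(counts) structure(counts, class = "atom_pair_multiset",
                                   scheme = "element+degree+aromatic")
  a <- ms(c(k1 = 2L, k2 = 1L))
  b <- ms(c(k1 = 1L, k3 = 1L))
  expect_equal(atom_pair_tanimoto(a, b), 1 / 4)
  expect_equal(atom_pair_tanimoto(a, a), 1)
  expect_equal(atom_pair_tanimoto(ms(c(k1 = 1L)), ms(c(k9 = 2L))), 0)
  expect_equal(atom_pair_tanimoto(ms(integer()), ms(integer())), 1)
  bad <- ms(c(k1 = 1L)); attr(bad, "scheme") <- "other"
  expect_error(atom_pair_tanimoto(a, bad), "schemes differ")

  # propane: pairs (CH3, CH2, 1) x2 and (CH3, CH3, 2) x1
  pr <- atom_pairs(parse_structure("CCC"))
  expect_equal(sum(pr), 3L)
  expect_length(pr, 2L)
})

test_that("MCS similarity handles the canonical small cases", {
  path3 <- molecular_graph(c("C", "C", "C"),
                           data.frame(a = c(1L, 2L), b = c(2L, 3L),
                                      order = c(1, 1)))
  path2 <- molecular_graph(c("C", "C"),
                           data.frame(a = 1L, b = 2L, order = 1))
  expect_equal(as.numeric(mcs_similarity(path3, path3)), 1)
  expect_equal(as.numeric(mcs_similarity(path3, path2)), 1 / 2)
  expect_equal(as.numeric(mcs_similarity(path2, path3)), 1 / 2)

  ring6 <- function(aromatic) {
    molecular_graph(rep("C", 6),
                    data.frame(a = 1:6, b = c(2:6, 1L),
                               order = if (aromatic) rep(1, 6) else rep(1, 6),
                               aromatic = rep(aromatic, 6)),
                    aromatic = rep(aromatic, 6))
  }
  # benzene vs cyclohexane: aromatic labels block every bond match
  expect_equal(as.numeric(mcs_similarity(ring6(TRUE), ring6(FALSE))), 0)

  single_atom <- molecular_graph("C")
  expect_equal(as.numeric(mcs_similarity(single_atom, single_atom)), 1)
  expect_equal(as.numeric(mcs_similarity(single_atom, path2)), 0)
  expect_error(mcs_similarity(single_atom, molecular_graph(character())),
               "at least one atom")
})

test_that("exact MCS agrees with brute-force enumeration on small graphs", {
  set.seed(77)
  for (i in 1:12) {
    ga <- random_toy_graph(sample(3:5, 1L), extra_edges = sample(0:2, 1L))
    gb <- random_toy_graph(sample(3:6, 1L), extra_edges = sample(0:2, 1L))
    if (nrow(ga$bonds) > 8L || nrow(gb$bonds) > 8L) next
    m <- mcs_similarity(ga, gb)
    expect_true(attr(m, "exact"))
    expect_equal(attr(m, "edges"), mces_oracle(ga, gb),
                 info = sprintf("case %d", i))
    expect_lte(attr(m, "edges"), min(nrow(ga$bonds), nrow(gb$bonds)))
  }
})

test_that("all three kernels are symmetric, bounded and reflexive", {
  smi <- ligand_smiles()[c("RBV", "Acadesine", "T-1106")]
  graphs <- lapply(names(smi), function(n) parse_structure(smi[[n]], n))
  fps <- lapply(graphs, path_fingerprint)
  aps <- lapply(graphs, atom_pairs)
  for (i in seq_along(graphs)) {
    expect_equal(tanimoto(fps[[i]], fps[[i]]), 1)
    expect_equal(atom_pair_tanimoto(aps[[i]], aps[[i]]), 1)
    expect_equal(as.numeric(mcs_similarity(graphs[[i]], graphs[[i]])), 1)
    for (j in seq_along(graphs)) {
      if (j >= i) next
      t1 <- tanimoto(fps[[i]], fps[[j]])
      expect_equal(t1, tanimoto(fps[[j]], fps[[i]]))
      expect_true(t1 >= 0 && t1 <= 1)
      a1 <- atom_pair_tanimoto(aps[[i]], aps[[j]])
      expect_equal(a1, atom_pair_tanimoto(aps[[j]], aps[[i]]))
      expect_true(a1 >= 0 && a1 <= 1)
      m1 <- as.numeric(mcs_similarity(graphs[[i]], graphs[[j]]))
      expect_equal(m1, as.numeric(mcs_similarity(graphs[[j]], graphs[[i]])))
      expect_true(m1 >= 0 && m1 <= 1)
    }
  }
})

test_that("the similarity panel compares every ligand to the reference", {
  smi <- c(ref = "CCO", eth = "CC", meth = "C")
  panel <- similarity_panel(smi, "ref", kernels = c("tanimoto", "mcs"))
  expect_equal(nrow(panel), 3L)
  expect_equal(panel$tanimoto[panel$ligand_id == "ref"], 1)
  expect_equal(panel$mcs[panel$ligand_id == "ref"], 1)
  expect_equal(panel$mcs[panel$ligand_id == "eth"], 0.5)
  expect_true(is.na(panel$atom_pair[1L]))
  expect_error(similarity_panel(unname(smi), "ref"), "named")
})
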