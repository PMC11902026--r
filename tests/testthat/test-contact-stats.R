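toy_cm <- function(m, el = rownames(m)) contact_matrix(m, elements = el)

test_that("surface fractions are half-sums of mixed contacts", {
  m1 <- matrix(100, 1, 1, dimnames = list("H", "H"))
  expect_equal(unname(as.numeric(surface_fractions(toy_cm(m1)))), 100)

  m2 <- matrix(c(25, 50, 50, 25), 2, 2, dimnames = list(c("H", "O"),
                                                        c("H", "O")))
  sf <- surface_fractions(toy_cm(m2))
  expect_equal(unname(as.numeric(sf)), c(50, 50))

  # three-element case against hand-computed half-sums:
  # S_C = 10 + (20 + 6)/2 = 23, S_H = 40 + (20 + 4)/2 = 52, S_O = 20+(6+4)/2=25
  m3 <- matrix(c(10, 20, 6,
                 20, 40, 4,
                 6, 4, 20), 3, 3, byrow = TRUE,
               dimnames = list(c("C", "H", "O"), c("C", "H", "O")))
  sf3 <- surface_fractions(toy_cm(m3))
  expect_equal(unname(as.numeric(sf3)), c(23, 52, 25))
})

test_that("contact matrices are validated", {
  m <- matrix(c(10, 20, 20, 40), 2, 2, dimnames = list(c("H", "O"),
                                                       c("H", "O")))
  expect_error(contact_matrix(m), "sum to")
  m2 <- matrix(c(25, 50, 49, 25), 2, 2, dimnames = list(c("H", "O"),
                                                        c("H", "O")))
  expect_error(contact_matrix(m2), "not symmetric")
  m3 <- matrix(c(25, -1, -1, 25), 2, 2, dimnames = list(c("H", "O"),
                                                        c("H", "O")))
  expect_error(contact_matrix(m3), "non-negative")
})

test_that("random-contact expectations follow the product rule", {
  expect_equal(unname(random_contacts(c(H = 100))), matrix(100, 1, 1))

  r <- random_contacts(c(H = 50, O = 50))
  expect_equal(unname(diag(r)), c(25, 25))
  expect_equal(r["H", "O"], 50)

  r2 <- random_contacts(c(H = 60, O = 40))
  expect_equal(r2["H", "H"], 36)
  expect_equal(r2["H", "O"], 48)
  expect_equal(r2["O", "O"], 16)

  expect_error(random_contacts(c(H = -5, O = 105)), "negative")
})

test_that("random-contact totals close to 100 for arbitrary compositions", {
  set.seed(41)
  for (i in 1:25) {
    k <- sample(2:5, 1L)
    s <- runif(k)
    s <- s / sum(s) * 100
    names(s) <- paste0("E", seq_len(k))
    r <- random_contacts(s)
    total <- sum(diag(r)) + sum(r[upper.tri(r)])
    expect_equal(total, 100, tolerance = 1e-12)
  }
})

test_that("enrichment ratios flag privileged and disfavored contacts", {
  m <- matrix(c(10, 80, 80, 10), 2, 2, dimnames = list(c("H", "O"),
                                                       c("H", "O")))
  e <- enrichment(toy_cm(m))
  expect_equal(e$enrichment[e$x == "H" & e$y == "O"], 1.6, tolerance = 1e-9)
  expect_equal(e$enrichment[e$x == "H" & e$y == "H"], 0.4, tolerance = 1e-9)
  expect_equal(e$classification[e$x == "H" & e$y == "O"], "privileged")
  expect_equal(e$classification[e$x == "H" & e$y == "H"], "disfavored")
})

test_that("a randomly structured surface has enrichment 1 everywhere", {
  set.seed(43)
  for (i in 1:10) {
    k <- sample(2:4, 1L)
    s <- runif(k, 0.5, 2)
    s <- s / sum(s) * 100
    names(s) <- paste0("E", seq_len(k))
    r <- random_contacts(s)
    e <- enrichment(contact_matrix(r))
    expect_equal(e$enrichment, rep(1, nrow(e)), tolerance = 1e-9)
    # and the E-weighted random proportions recover the observed contacts
    expect_equal(sum(e$enrichment * e$random_pct), 100, tolerance = 1e-9)
  }
})

test_that("sparse pairs are flagged rather than reported as stable ratios", {
  m <- matrix(c(97, 1.0, 1.0, 1.0), 2, 2,
              dimnames = list(c("H", "F"), c("H", "F")))
  e <- enrichment(toy_cm(m), sparse_threshold = 0.5)
  expect_true(e$sparse[e$x == "F" & e$y == "F"])
  expect_false(e$sparse[e$x == "H" & e$y == "H"])
})

test_that("contribution RMSD applies the zero-fill/union convention", {
  nt <- nitrogen_contact_table()
  ref <- nt[["Ribavirin form II"]]
  expect_equal(round(contribution_rmsd(nt[["Ribavirin form I"]], ref), 2),
               4.86)
  expect_equal(round(contribution_rmsd(nt[["Acadesine"]], ref), 2), 4.36)
  expect_equal(contribution_rmsd(ref, ref), 0)

  # channels named only on one side are zero-filled but still counted
  a <- c(x = 3, y = 0)
  b <- c(y = 0, z = 0)
  expect_equal(contribution_rmsd(a, b), sqrt(9 / 3))
  expect_error(contribution_rmsd(numeric(), numeric()), "empty")
  expect_error(contribution_rmsd(c(x = -1), c(x = 1)), "non-negative")
})

test_that("Euclidean distance relates to RMSD by sqrt(n) exactly", {
  a <- c(p = 1, q = 5)
  expect_equal(contribution_euclidean(a, a), 0)
  expect_equal(contribution_euclidean(c(p = 4), c(p = 1)), 3)

  set.seed(47)
  for (i in 1:30) {
    n <- sample(2:6, 1L)
    a <- stats::setNames(runif(n, 0, 60), paste0("c", seq_len(n)))
    drop <- sample(n, 1L)
    b <- stats::setNames(runif(n, 0, 60), paste0("c", seq_len(n)))[-drop]
    expect_equal(contribution_euclidean(a, b),
                 contribution_rmsd(a, b) * sqrt(n), tolerance = 1e-12)
  }
})
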