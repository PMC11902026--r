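test_that("solid-state indices reproduce published shifts", {
  # ribavirin form II amide nitrogen
  ctx <- context_params("-NH2", single = c(3.758, 0.070),
                        solid = c(2.629, 0.750))
  s <- solid_state_indices(ctx)
  expect_equal(unname(s["delta_s"]), -1.129, tolerance = 1e-9)
  expect_equal(unname(s["small_delta_s"]), 0.68, tolerance = 1e-9)

  # favipiravir form I amide nitrogen
  ctx2 <- context_params("-NH2", single = c(2.968, 0.51),
                         solid = c(2.336, 0.81))
  s2 <- solid_state_indices(ctx2)
  expect_equal(unname(s2["delta_s"]), -0.632, tolerance = 1e-9)
  expect_equal(unname(s2["small_delta_s"]), 0.30, tolerance = 1e-9)

  same <- context_params("x", single = c(3, 0.4), solid = c(3, 0.4))
  expect_equal(unname(solid_state_indices(same)), c(0, 0))
})

test_that("complexation indices reproduce published shifts", {
  ctx <- context_params("-NH2", single = c(4.212, 0.230),
                        complex = c(2.742, 0.610))
  cc <- complexation_indices(ctx)
  expect_equal(unname(cc["delta_c"]), -1.47, tolerance = 1e-9)
  expect_equal(unname(cc["small_delta_c"]), 0.38, tolerance = 1e-9)

  ctx2 <- context_params("N(1)", single = c(2.283, 0.400),
                         complex = c(1.989, 0.180))
  cc2 <- complexation_indices(ctx2)
  expect_equal(unname(cc2["delta_c"]), -0.294, tolerance = 1e-9)
  expect_equal(unname(cc2["small_delta_c"]), -0.22, tolerance = 1e-9)
})

test_that("solid-vs-complex indices reproduce published shifts", {
  ctx <- context_params("N(4)", solid = c(3.188, 0.370),
                        complex = c(4.519, 0.090))
  cs <- solid_vs_complex_indices(ctx)
  expect_equal(unname(cs["delta_cs"]), 1.331, tolerance = 1e-9)
  expect_equal(unname(cs["small_delta_cs"]), -0.28, tolerance = 1e-9)

  ctx2 <- context_params("-NH2", solid = c(2.629, 0.750),
                         complex = c(2.742, 0.610))
  cs2 <- solid_vs_complex_indices(ctx2)
  expect_equal(unname(cs2["delta_cs"]), 0.113, tolerance = 1e-9)
  expect_equal(unname(cs2["small_delta_cs"]), -0.14, tolerance = 1e-9)
})

test_that("missing contexts raise explicit errors, never silent zeros", {
  ctx <- context_params("x", single = c(3, 0.2), solid = c(2.8, 0.3))
  expect_error(complexation_indices(ctx), "missing context `complex`")
  expect_error(solid_vs_complex_indices(ctx), "missing context `complex`")
  expect_error(context_params("x", single = c(3, 0.2)), "at least two")
})

test_that("index operations are antisymmetric in their two contexts", {
  set.seed(21)
  for (i in 1:20) {
    a <- c(runif(1, 2, 5), runif(1))
    b <- c(runif(1, 2, 5), runif(1))
    fwd <- solid_state_indices(context_params("s", single = a, solid = b))
    rev <- solid_state_indices(context_params("s", single = b, solid = a))
    expect_equal(unname(fwd), -unname(rev), tolerance = 1e-12)
    fwd_c <- solid_vs_complex_indices(context_params("s", solid = a,
                                                     complex = b))
    rev_c <- solid_vs_complex_indices(context_params("s", solid = b,
                                                     complex = a))
    expect_equal(unname(fwd_c), -unname(rev_c), tolerance = 1e-12)
  }
})

test_that("with a shared single-molecule reference the indices telescope", {
  set.seed(22)
  for (i in 1:20) {
    ctx <- context_params("s",
                          single = c(runif(1, 2, 5), runif(1)),
                          solid = c(runif(1, 2, 5), runif(1)),
                          complex = c(runif(1, 2, 5), runif(1)))
    s <- solid_state_indices(ctx)
    cc <- complexation_indices(ctx)
    cs <- solid_vs_complex_indices(ctx)
    expect_equal(unname(cs["delta_cs"]),
                 unname(cc["delta_c"] - s["delta_s"]), tolerance = 1e-9)
    expect_equal(unname(cs["small_delta_cs"]),
                 unname(cc["small_delta_c"] - s["small_delta_s"]),
                 tolerance = 1e-9)
    expect_true(abs(cs["small_delta_cs"]) <= 1)
  }
})

test_that("tabulation reports absent indices as NA and rejects duplicates", {
  full <- context_params("a", single = c(3, 0.1), solid = c(2.5, 0.2),
                         complex = c(2.8, 0.3))
  partial <- context_params("b", single = c(4, 0.5), solid = c(3.9, 0.6))
  tab <- tabulate_indices(list(full, partial))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$delta_cs[1L], tab$delta_c[1L] - tab$delta_s[1L],
               tolerance = 1e-9)
  expect_true(is.na(tab$delta_c[2L]) && is.na(tab$delta_cs[2L]))
  expect_false(is.na(tab$delta_s[2L]))

  expect_error(tabulate_indices(list(full, full)), "duplicate site labels")
  expect_error(tabulate_indices(list()), "no context records")
})

test_that("the bundled per-context table reproduces the published columns", {
  ctx <- nqr_context_table()
  s <- solid_state_indices(ctx[["RBV form I: -NH2"]])
  expect_equal(unname(s), c(-0.658, -0.08), tolerance = 1e-9)
  cc <- complexation_indices(ctx[["RBV complex: >N-sugar"]])
  expect_equal(unname(cc), c(-0.008, -0.129), tolerance = 1e-9)
})
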