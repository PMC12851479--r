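test_that("simulation is seed-deterministic and closed to kappa", {
  d1 <- simulate_cmrlmm(n_subjects = 15, seed = 3)
  d2 <- simulate_cmrlmm(n_subjects = 15, seed = 3)
  expect_identical(d1, d2)
  d3 <- simulate_cmrlmm(n_subjects = 15, seed = 4)
  expect_false(identical(d1, d3))
  B <- as.matrix(d1[, loh_basis()$labels])
  expect_true(all(B > 0))
  expect_equal(unname(rowSums(B)), rep(1440, nrow(B)))
})

test_that("fixtures have the documented shapes", {
  tiny <- make_fixture("tiny", seed = 1)
  expect_equal(nrow(tiny), 18L) # 6 subjects x 3 occasions
  expect_equal(nrow(stack_olr(compute_olr(tiny, loh_basis()))), 54L)
  loh <- make_fixture("loh_like", seed = 1)
  expect_equal(nrow(loh), 1205L) # 241 x 5, no missingness
  expect_setequal(names(loh),
                  c("id", "occasion", "zbmi", "income", loh_basis()$labels))
  null <- make_fixture("null_effects", seed = 1, n_subjects = 30)
  expect_equal(attr(null, "truth")$beta[-1, ], 0 * attr(null, "truth")$beta[-1, ])
  diagt <- make_fixture("diagonal_truth", seed = 1, n_subjects = 30)
  expect_equal(attr(diagt, "truth")$G, diag(diag(attr(diagt, "truth")$G)),
               ignore_attr = TRUE)
  expect_error(make_fixture("nope"), "arg")
})

test_that("missingness removes occasions but never a subject's first", {
  d <- simulate_cmrlmm(n_subjects = 100, covariates = "none",
                       beta = loh_params()$beta[1:5, ], missingness = 0.2,
                       seed = 6)
  expect_lt(nrow(d), 500)
  expect_gt(nrow(d), 300)
  first <- tapply(as.character(d$occasion), d$id, function(x) "T1" %in% x)
  expect_true(all(first))
})

test_that("simulated moments match the generating covariances", {
  p <- loh_params()
  d <- simulate_cmrlmm(n_subjects = 1000, covariates = "none",
                       beta = p$beta[1:5, ], seed = 13)
  o <- compute_olr(d, p$basis)
  Z <- as.matrix(o[, c("z1", "z2", "z3")])
  X <- stats::model.matrix(~ occasion, o)
  res <- stats::lm.fit(X, Z)$residuals
  M <- apply(res, 2, function(col) tapply(col, o$id, mean))
  within <- res - M[as.character(o$id), ]
  E_hat <- crossprod(within) / (nrow(d) - 1000)
  expect_lt(max(abs(E_hat - p$E)), 0.006)
  # between-subject covariance of occasion means is G + E/J
  G_hat <- stats::cov(M) - p$E / 5
  expect_lt(max(abs(G_hat - p$G)), 0.012)
})

test_that("the noise-free limit collapses to the intercept composition", {
  p <- loh_params()
  b0 <- p$beta[1:2, ]
  b0[2, ] <- 0 # no timepoint effect
  d <- simulate_cmrlmm(n_subjects = 5, occasions = paste0("T", 1:2),
                       beta = b0,
                       G = diag(1e-12, 3), E = diag(1e-12, 3),
                       basis = p$basis, covariates = "none", seed = 2)
  ref <- parts(olr_inv(p$beta[1, ], p$basis, 1440))
  B <- as.matrix(d[, p$basis$labels])
  # coordinate noise has sd 1e-6, i.e. ~1e-3 min after back-transformation
  expect_lt(max(abs(sweep(B, 2, ref))), 1e-2)
})

test_that("invalid generator inputs are refused", {
  p <- loh_params()
  badG <- p$G; badG[1, 2] <- badG[2, 1] <- 1 # correlation > 1
  expect_error(simulate_cmrlmm(n_subjects = 5, G = badG, seed = 1),
               "positive definite")
  badbeta <- p$beta[c(2, 1, 3:8), ]
  expect_error(simulate_cmrlmm(n_subjects = 5, beta = badbeta, seed = 1),
               "rownames")
})
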