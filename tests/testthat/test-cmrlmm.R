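test_that("the reference specification has the expected parameter counts", {
  # D = 4, five categorical timepoints, zbmi, 3-level income:
  # 8 fixed effects x 3 coordinates + 6 + 6 covariance parameters
  expect_equal(fit_medium$n_fixed, 24L)
  expect_equal(fit_medium$n_params, 36L)
  expect_equal(fit_medium_diag$n_params, 30L)
  expect_equal(fit_medium$n_params - fit_medium_diag$n_params, 6L)
})

test_that("the full covariance fit dominates the diagonal fit in likelihood", {
  expect_gte(fit_medium$loglik, fit_medium_diag$loglik)
  tst <- lrt(fit_medium, fit_medium_diag)
  expect_gte(tst$statistic, 0)
  expect_equal(tst$df, 6L)
})

test_that("diagonal-constrained fit equals separate univariate fits", {
  us <- univariate_suite(time_use_formula, medium_data, subject = "id",
                         basis = time_use_basis, kappa = 1440)
  expect_equal(unname(coef_matrix(fit_medium_diag)), unname(suite_coef(us)),
               tolerance = 1e-6)
  expect_equal(unname(diag(fit_medium_diag$G)),
               unname(vapply(us$fits, `[[`, numeric(1), "sigma2")),
               tolerance = 1e-4)
})

test_that("continuous time gives one slope per coordinate", {
  p <- loh_params()
  beta <- rbind("(Intercept)" = p$beta[1, ], occasion = c(0.01, 0.03, 0.02))
  d <- simulate_cmrlmm(n_subjects = 40, occasions = 0:4, beta = beta,
                       G = p$G, E = p$E, basis = p$basis,
                       covariates = "none", seed = 8)
  fit <- cmrlmm(time_only_formula, d, subject = "id", basis = p$basis,
                kappa = 1440)
  expect_equal(fit$n_fixed, 6L) # (intercept + slope) x 3 coordinates
  expect_equal(fit$n_params, 18L)
  expect_equal(joint_test(fit, "occasion")$num_df, 3L)
})

test_that("fitted values, residuals and BLUPs are coherent", {
  Zhat_m <- fitted(fit_medium, level = "marginal")
  Zhat_c <- fitted(fit_medium, level = "conditional")
  res_c <- residuals(fit_medium)
  o <- compute_olr(medium_data, time_use_basis)
  Z <- as.matrix(o[, c("z1", "z2", "z3")])
  expect_equal(Zhat_c + res_c, Z, tolerance = 1e-10, ignore_attr = TRUE)
  b <- ranef(fit_medium)
  expect_equal(dim(b), c(60L, 3L))
  # BLUPs average near zero per coordinate (shrunken, centred)
  expect_lt(max(abs(colMeans(b))), 0.05)
  expect_equal(Zhat_c - Zhat_m,
               b[as.character(medium_data$id), ], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("predictions at the reference setting equal the intercept composition", {
  grid <- reference_grid(fit_medium, by = "occasion")
  nd <- grid$data[grid$data$occasion == "T1", , drop = FALSE]
  nd$zbmi <- 0
  pc <- predict_composition(fit_medium, nd)
  ic <- compositional_coef(fit_medium)
  intercept <- unlist(ic[ic$term == "(Intercept)", fit_medium$parts])
  expect_equal(unname(parts(pc)), unname(intercept), tolerance = 1e-9)
  # every predicted composition closes to kappa
  all_pc <- predict(fit_medium, newdata = grid$data, type = "composition")
  expect_equal(unname(rowSums(all_pc)), rep(1440, nrow(all_pc)))
  # unseen factor levels are refused
  bad <- grid$data[1, ]
  bad$occasion <- factor("T9", levels = c(levels(grid$data$occasion), "T9"))
  expect_error(predict(fit_medium, newdata = bad))
})

test_that("simulate() regenerates data with the model's own structure", {
  sims <- simulate(fit_medium, nsim = 2, seed = 123)
  expect_length(sims, 2L)
  s <- sims[[1]]
  expect_equal(dim(s), dim(medium_data))
  expect_equal(unname(rowSums(s[, fit_medium$parts])),
               rep(1440, nrow(s)))
  expect_false(identical(s$sleep, medium_data$sleep))
})

test_that("print and summary run quietly and carry the key quantities", {
  expect_output(print(fit_medium), "Compositional multivariate-response")
  s <- summary(fit_medium)
  expect_output(print(s), "Joint multivariate F tests")
  expect_equal(s$tests$estimate, unname(fit_medium$beta))
  expect_equal(sqrt(diag(fit_medium$vcov_beta)), fit_medium$beta / s$tests$t,
               tolerance = 1e-10, ignore_attr = TRUE)
})
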