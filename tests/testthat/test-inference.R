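test_that("a rank-1 joint test is the squared t test", {
  # with a 2-part composition there is a single coordinate, so each term
  # block has exactly one coefficient
  p <- loh_params()
  b2 <- sbp_basis(matrix(c(1, -1), 1, 2), labels = c("active", "passive"))
  d <- simulate_cmrlmm(n_subjects = 40, occasions = paste0("T", 1:3),
                       beta = rbind("(Intercept)" = 0.4, occasionT2 = 0.1,
                                    occasionT3 = 0.05),
                       G = matrix(0.05, 1, 1), E = matrix(0.08, 1, 1),
                       basis = b2, covariates = "none", seed = 12)
  fit <- cmrlmm(cbind(active, passive) ~ occasion, d, subject = "id",
                basis = b2, kappa = 1440)
  ct <- coef_tests(fit)
  jt <- joint_test(fit, "(Intercept)")
  expect_equal(jt$num_df, 1L)
  expect_equal(jt$statistic, ct["z1:(Intercept)", "t"]^2, tolerance = 1e-8)
  expect_equal(jt$den_df, ct["z1:(Intercept)", "df"])
})

test_that("standard errors come from the coefficient covariance diagonal", {
  ct <- coef_tests(fit_medium)
  expect_equal(ct$se, unname(sqrt(diag(vcov(fit_medium)))))
  expect_true(all(ct$p >= 0 & ct$p <= 1))
})

test_that("block structure drives the numerator df", {
  jt <- joint_tests(fit_medium)
  expect_equal(jt$term, c("Z", "Z:occasion", "Z:zbmi", "Z:income"))
  expect_equal(jt$num_df, c(3L, 12L, 3L, 6L))
  expect_true(all(jt$statistic >= 0))
  # the chi-square variant scales the F by its numerator df
  jc <- joint_tests(fit_medium, chisq = TRUE)
  expect_equal(jc$statistic, jt$statistic * jt$num_df, tolerance = 1e-10)
  # with the large den_df here the two p-values agree closely
  expect_equal(jc$p_value, jt$p_value, tolerance = 5e-2)
  expect_error(joint_test(fit_medium, "nope"), "unknown term")
})

test_that("likelihood-ratio testing enforces comparability", {
  expect_error(
    lrt(fit_medium,
        cmrlmm(time_only_formula, medium_data, subject = "id",
               basis = time_use_basis, kappa = 1440)),
    "not comparable")
  ml1 <- cmrlmm(time_use_formula, medium_data, subject = "id",
                basis = time_use_basis, kappa = 1440, method = "ML")
  expect_error(lrt(ml1, fit_medium), "different estimation methods")
  # identical models: zero statistic, p = 1
  same <- lrt(fit_medium, fit_medium)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # ML fixed-effect comparison is allowed and nested
  ml0 <- cmrlmm(time_only_formula, medium_data, subject = "id",
                basis = time_use_basis, kappa = 1440, method = "ML")
  tst <- lrt(ml1, ml0)
  expect_equal(tst$df, 9L) # zbmi + 2 income columns x 3 coordinates
  expect_gte(tst$statistic, 0)
})

test_that("anova on two fits reports the comparison table", {
  tab <- anova(fit_medium, fit_medium_diag)
  expect_equal(tab$n_params, c(36L, 30L))
  expect_equal(tab$df[1], 6L)
  expect_equal(tab$logLik,
               c(fit_medium$loglik, fit_medium_diag$loglik))
  expect_equal(tab$AIC, -2 * tab$logLik + 2 * tab$n_params)
})

test_that("per-coordinate t tests hold their size under the null", {
  # small two-part design so each replicate fits in milliseconds
  b2 <- sbp_basis(matrix(c(1, -1), 1, 2), labels = c("active", "passive"))
  nrep <- 200
  reject <- logical(nrep)
  for (k in seq_len(nrep)) {
    d <- simulate_cmrlmm(n_subjects = 25, occasions = paste0("T", 1:3),
                         beta = rbind("(Intercept)" = 0.4, occasionT2 = 0,
                                      occasionT3 = 0),
                         G = matrix(0.05, 1, 1), E = matrix(0.08, 1, 1),
                         basis = b2, covariates = "none", seed = 5000 + k)
    fit <- suppressWarnings(
      cmrlmm(cbind(active, passive) ~ occasion, d, subject = "id",
             basis = b2, kappa = 1440,
             control = cmrlmm_control(polish = FALSE)))
    reject[k] <- coef_tests(fit)["z1:occasionT2", "p"] < 0.05
  }
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.09)
})
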