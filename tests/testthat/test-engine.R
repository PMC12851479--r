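test_that("the optimised criterion matches a dense MVN oracle on small data", {
  d <- make_fixture("tiny", seed = 2)
  for (method in c("REML", "ML")) {
    fit <- suppressWarnings(
      cmrlmm(time_only_formula, d, subject = "id", basis = time_use_basis,
             kappa = 1440, method = method))
    expect_equal(loglik_oracle(fit), fit$loglik, tolerance = 1e-6)
    expect_equal(gls_oracle(fit), fit$beta, tolerance = 1e-6)
    # the oracle detects worse parameter values
    G2 <- fit$G + diag(0.05, 3)
    expect_lt(loglik_oracle(fit, G = G2), fit$loglik)
  }
})

test_that("the oracle reduces to iid normal densities in the no-pooling limit", {
  set.seed(10)
  b <- time_use_basis
  z <- matrix(rnorm(6), 2, 3) # 2 subjects x 1 occasion, 3 coordinates
  comp <- exp(z %*% t(b$contrast))
  comp <- comp * (1440 / rowSums(comp))
  d <- data.frame(id = c("a", "b"), occasion = "T1", comp)
  names(d)[3:6] <- b$labels
  fit <- suppressWarnings(
    cmrlmm(cbind(sleep, sb, lpa, mvpa) ~ 1, d, subject = "id", basis = b,
           kappa = 1440, method = "ML"))
  beta0 <- rep(0, 3)
  names(beta0) <- names(fit$beta)
  ll <- loglik_oracle(fit, beta = beta0, G = diag(1e-10, 3), E = diag(3),
                      method = "ML")
  expect_equal(ll, sum(dnorm(z, log = TRUE)), tolerance = 1e-6)
})

test_that("the likelihood is invariant to subject order and response labels", {
  d <- make_fixture("loh_like", seed = 21, n_subjects = 30)
  f1 <- cmrlmm(time_use_formula, d, subject = "id", basis = time_use_basis,
               kappa = 1440)
  set.seed(1)
  d2 <- d[sample(nrow(d)), ]
  f2 <- cmrlmm(time_use_formula, d2, subject = "id", basis = time_use_basis,
               kappa = 1440)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
  # relabel responses: permuting basis columns permutes the coordinates
  V <- time_use_basis$contrast[, c(2, 1, 3)]
  f3 <- cmrlmm(time_use_formula, d, subject = "id",
               basis = custom_basis(V, time_use_basis$labels), kappa = 1440)
  expect_equal(f3$loglik, f1$loglik, tolerance = 1e-6)
})

test_that("estimates agree with an independent stacked nlme fit", {
  skip_if_not_installed("nlme")
  d <- make_fixture("loh_like", seed = 7, n_subjects = 50)
  fit <- cmrlmm(time_use_formula, d, subject = "id", basis = time_use_basis,
                kappa = 1440)
  st <- stack_olr(compute_olr(d, time_use_basis))
  st$occ_id <- interaction(st$id, st$occasion, drop = TRUE)
  lf <- suppressWarnings(nlme::lme(
    olr_value ~ 0 + response + response:(occasion + zbmi + income),
    random = list(id = nlme::pdSymm(~ 0 + response)),
    weights = nlme::varIdent(form = ~ 1 | response),
    correlation = nlme::corSymm(form = ~ as.integer(response) | id / occ_id),
    data = st, method = "REML",
    control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                               opt = "optim", returnObject = TRUE)))
  expect_equal(unclass(logLik(lf))[1], fit$loglik, tolerance = 1e-6)
  fe <- nlme::fixef(lf)
  bm <- coef_matrix(fit)
  nl <- sapply(1:3, function(r) sapply(rownames(bm), function(tm) {
    nm <- if (tm == "(Intercept)") paste0("responsez", r) else
      paste0("responsez", r, ":", tm)
    unname(fe[nm])
  }))
  expect_equal(unname(bm), unname(nl), tolerance = 1e-6)
  G_nlme <- as.matrix(nlme::getVarCov(lf))
  expect_equal(unclass(G_nlme), unclass(fit$G), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("unbalanced data (20% missing occasions) still recover parameters", {
  p <- loh_params()
  d <- simulate_cmrlmm(n_subjects = 300, covariates = "loh",
                       missingness = 0.2, seed = 31)
  expect_lt(nrow(d), 1500)
  fit <- cmrlmm(time_use_formula, d, subject = "id", basis = p$basis,
                kappa = 1440)
  expect_true(fit$converged)
  expect_lt(max(abs(diag(fit$G) - diag(p$G)) / diag(p$G)), 0.25)
  expect_lt(max(abs(diag(fit$E) - diag(p$E)) / diag(p$E)), 0.15)
  expect_lt(max(abs(coef_matrix(fit)["(Intercept)", ] -
                      p$beta["(Intercept)", ])), 0.06)
})

test_that("rank-deficient designs fail with the aliased column named", {
  d <- make_fixture("loh_like", seed = 5, n_subjects = 20)
  d$zbmi2 <- d$zbmi
  expect_error(
    cmrlmm(cbind(sleep, sb, lpa, mvpa) ~ occasion + zbmi + zbmi2, d,
           subject = "id", basis = time_use_basis, kappa = 1440),
    "zbmi2")
})
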