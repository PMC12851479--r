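#' Reference parameters for the longitudinal child time-use study design
#'
#' Default generator settings emulating a longitudinal cohort of primary
#' school children measured at five timepoints over two school years: a
#' 4-part composition (sleep, SB, LPA, MVPA) expressed in the balance basis
#' of [loh_basis()], fixed effects for categorical timepoint (contrasts to
#' timepoint 1), standardised BMI and a 3-level parental income category,
#' and unstructured between-subject (G) and residual (E) covariance across
#' the three coordinates (standard deviations 0.11/0.29/0.22 with
#' correlations 0.75/0.64/0.49, and 0.12/0.24/0.26 with correlations
#' 0.68/0.64/0.64 respectively).
#'
#' @return A list with elements `beta` (term-by-coordinate matrix), `G`,
#'   `E`, `basis`, `occasions`, `n_subjects` and `kappa`.
#' @export
loh_params <- function() {
  basis <- loh_basis()
  beta <- rbind(
    "(Intercept)" = c(0.83, 0.94, 0.93),
    "occasionT2"  = c(0.01, 0.01, -0.01),
    "occasionT3"  = c(0.09, 0.22, 0.21),
    "occasionT4"  = c(0.03, 0.09, 0.01),
    "occasionT5"  = c(0.04, 0.12, 0.05),
    "zbmi"        = c(0.01, 0.003, 0.05),
    "incomehigh"  = c(-0.001, 0.01, -0.07),
    "incomelow"   = c(0.03, 0.10, 0.03))
  colnames(beta) <- colnames(basis$contrast)
  sd_g <- c(0.11, 0.29, 0.22)
  cor_g <- diag(3)
  cor_g[1, 2] <- cor_g[2, 1] <- 0.75
  cor_g[1, 3] <- cor_g[3, 1] <- 0.64
  cor_g[2, 3] <- cor_g[3, 2] <- 0.49
  G <- diag(sd_g) %*% cor_g %*% diag(sd_g)
  sd_e <- c(0.12, 0.24, 0.26)
  cor_e <- diag(3)
  cor_e[1, 2] <- cor_e[2, 1] <- 0.68
  cor_e[1, 3] <- cor_e[3, 1] <- 0.64
  cor_e[2, 3] <- cor_e[3, 2] <- 0.64
  E <- diag(sd_e) %*% cor_e %*% diag(sd_e)
  dimnames(G) <- dimnames(E) <- list(colnames(basis$contrast),
                                     colnames(basis$contrast))
  list(beta = beta, G = G, E = E, basis = basis,
       occasions = paste0("T", 1:5), n_subjects = 241L, kappa = 1440)
}

#' The sleep / SB / LPA / MVPA balance basis
#'
#' Sequential binary partition: sleep vs all waking behaviours, SB vs active
#' behaviours (LPA + MVPA), LPA vs MVPA.
#'
#' @return An `"olr_basis"` over parts `sleep, sb, lpa, mvpa`.
#' @export
loh_basis <- function() {
  sbp_basis(rbind(c(1, -1, -1, -1),
                  c(0, 1, -1, -1),
                  c(0, 0, 1, -1)),
            labels = c("sleep", "sb", "lpa", "mvpa"))
}

#' An alternative balance basis over the same parts
#'
#' Splits waking-activity groups first ((sleep, mvpa) vs (sb, lpa)), then
#' within groups; used to demonstrate basis invariance of the
#' full-covariance model.
#'
#' @return An `"olr_basis"` over parts `sleep, sb, lpa, mvpa`.
#' @export
alt_basis <- function() {
  sbp_basis(rbind(c(1, -1, -1, 1),
                  c(1, 0, 0, -1),
                  c(0, 1, -1, 0)),
            labels = c("sleep", "sb", "lpa", "mvpa"))
}

#' Simulate multilevel compositional time-use data
#'
#' Generates long-format data with exactly the generative structure the
#' model assumes: per subject a random-intercept vector `b_i ~ MVN(0, G)`,
#' per subject-occasion a residual vector `e_ij ~ MVN(0, E)`, coordinates
#' `z_ij = x_ij' beta + b_i + e_ij`, and behaviours `olr_inv(z_ij)` closed
#' to `kappa`. Covariates follow simple invented but documented
#' distributions: `zbmi` standard normal and `income` categorical with
#' probabilities 0.5/0.3/0.2 for middle/high/low (both time-invariant).
#'
#' @param n_subjects number of subjects.
#' @param occasions character vector of occasion labels (categorical time)
#'   or numeric times (continuous time, single slope per coordinate).
#' @param beta term-by-coordinate fixed-effect matrix; rownames must match
#'   the design columns implied by `occasions` and `covariates`.
#' @param G,E coordinate covariance matrices (between-subject and residual).
#' @param basis `"olr_basis"` defining the coordinates and part labels.
#' @param covariates `"loh"` for the zbmi + income model, or `"none"`.
#' @param missingness per-occasion MCAR dropout probability (occasion 1 is
#'   always kept so every subject is observed at least once).
#' @param kappa closure constant of the generated behaviours.
#' @param seed optional integer seed.
#' @return A long data.frame with columns `id`, `occasion`, covariates and
#'   one column per part; the generating parameters and the drawn random
#'   intercepts are attached as attribute `"truth"`.
#' @examples
#' d <- simulate_cmrlmm(n_subjects = 20, seed = 1)
#' head(d)
#' @export
simulate_cmrlmm <- function(n_subjects = 241L,
                            occasions = paste0("T", 1:5),
                            beta = loh_params()$beta,
                            G = loh_params()$G,
                            E = loh_params()$E,
                            basis = loh_basis(),
                            covariates = c("loh", "none"),
                            missingness = 0,
                            kappa = 1440,
                            seed = NULL) {
  covariates <- match.arg(covariates)
  if (!is.null(seed)) set.seed(seed)
  R <- ncol(basis$contrast)
  stopifnot(nrow(G) == R, nrow(E) == R)
  check_pd <- function(M, nm) {
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop(nm, " must be positive definite")
  }
  check_pd(G, "G"); check_pd(E, "E")
  J <- length(occasions)
  ids <- sprintf("S%04d", seq_len(n_subjects))
  long <- data.frame(
    id = rep(ids, each = J),
    occasion = if (is.numeric(occasions)) rep(occasions, n_subjects) else
      factor(rep(occasions, n_subjects), levels = occasions),
    stringsAsFactors = FALSE)
  if (covariates == "loh") {
    zbmi <- stats::rnorm(n_subjects)
    income <- sample(c("middle", "high", "low"), n_subjects, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))
    long$zbmi <- rep(zbmi, each = J)
    long$income <- factor(rep(income, each = J),
                          levels = c("middle", "high", "low"))
    rhs <- ~ occasion + zbmi + income
  } else {
    rhs <- ~ occasion
  }
  X0 <- stats::model.matrix(rhs, long)
  if (!identical(colnames(X0), rownames(beta))) {
    stop("rownames(beta) must be: ", paste(colnames(X0), collapse = ", "))
  }
  b <- matrix(stats::rnorm(n_subjects * R), ncol = R) %*% chol(G)
  eps <- matrix(stats::rnorm(nrow(long) * R), ncol = R) %*% chol(E)
  z <- X0 %*% beta + b[rep(seq_len(n_subjects), each = J), ] + eps
  comp <- exp(z %*% t(basis$contrast))
  comp <- comp * (kappa / rowSums(comp))
  colnames(comp) <- basis$labels
  long <- cbind(long, as.data.frame(comp))
  if (missingness > 0) {
    drop <- stats::runif(nrow(long)) < missingness
    drop[seq(1L, nrow(long), by = J)] <- FALSE # keep first occasion
    long <- long[!drop, , drop = FALSE]
    rownames(long) <- NULL
  }
  rownames(b) <- ids
  attr(long, "truth") <- list(beta = beta, G = G, E = E, basis = basis,
                              kappa = kappa, b = b, rhs = rhs)
  long
}

#' Canned seeded simulation scenarios
#'
#' * `tiny`: 6 subjects x 3 occasions, no covariates - small enough for
#'   dense-likelihood oracle checks.
#' * `loh_like`: the full reference design of [loh_params()] (241 x 5 with
#'   zbmi and income).
#' * `null_effects`: as `loh_like` but without covariates and with all
#'   timepoint effects set to zero - for type-I error calibration of the
#'   joint time test.
#' * `diagonal_truth`: as `null_effects` but with time effects retained and
#'   all G and E correlations zeroed - for null calibration of the
#'   likelihood-ratio test on the covariance structure.
#'
#' @param name scenario name.
#' @param seed integer seed.
#' @param n_subjects override the scenario's subject count (scenarios other
#'   than `tiny`).
#' @return A long data.frame as from [simulate_cmrlmm()].
#' @export
make_fixture <- function(name = c("tiny", "loh_like", "null_effects",
                                  "diagonal_truth"),
                         seed = 20260101, n_subjects = NULL) {
  name <- match.arg(name)
  p <- loh_params()
  time_beta <- p$beta[1:5, , drop = FALSE] # intercept + T2..T5
  switch(name,
    tiny = simulate_cmrlmm(
      n_subjects = 6L, occasions = paste0("T", 1:3),
      beta = time_beta[1:3, , drop = FALSE],
      G = p$G, E = p$E, basis = p$basis, covariates = "none",
      kappa = p$kappa, seed = seed),
    loh_like = simulate_cmrlmm(
      n_subjects = if (is.null(n_subjects)) p$n_subjects else n_subjects,
      occasions = p$occasions, beta = p$beta, G = p$G, E = p$E,
      basis = p$basis, covariates = "loh", kappa = p$kappa, seed = seed),
    null_effects = {
      b0 <- time_beta
      b0[-1L, ] <- 0
      simulate_cmrlmm(
        n_subjects = if (is.null(n_subjects)) p$n_subjects else n_subjects,
        occasions = p$occasions, beta = b0, G = p$G, E = p$E,
        basis = p$basis, covariates = "none", kappa = p$kappa, seed = seed)
    },
    diagonal_truth = simulate_cmrlmm(
      n_subjects = if (is.null(n_subjects)) p$n_subjects else n_subjects,
      occasions = p$occasions, beta = time_beta,
      G = diag(diag(p$G)), E = diag(diag(p$E)),
      basis = p$basis, covariates = "none", kappa = p$kappa, seed = seed))
}
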