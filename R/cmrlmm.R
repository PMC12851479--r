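#' Fit a compositional multivariate-response linear mixed model
#'
#' Expresses a D-part compositional response (e.g. daily minutes of sleep,
#' SB, LPA and MVPA) as D-1 orthonormal log-ratio coordinates and fits all
#' coordinates jointly: every fixed-effect term is interacted with the
#' response coordinate (there is no pooled intercept), each subject gets a
#' correlated random-intercept vector `b_i ~ MVN(0, G)` across coordinates,
#' and the residual vector within a subject-occasion is `MVN(0, E)`. With
#' unstructured G and E the fit is invariant (after back-transformation) to
#' the olr basis used; constraining both to diagonal reproduces the common
#' but basis-dependent practice of fitting each coordinate separately.
#'
#' Estimation maximises the restricted (REML, default) or full (ML)
#' likelihood over a log-Cholesky parameterisation of G and E, with the
#' fixed effects profiled out by generalised least squares. Use ML when the
#' fit will be compared by likelihood ratio to a model with different fixed
#' effects; REML comparisons are only valid between covariance structures
#' with identical fixed effects.
#'
#' @param formula a formula whose left-hand side names the behaviour columns
#'   via `cbind()`, e.g. `cbind(sleep, sb, lpa, mvpa) ~ occasion + zbmi`.
#'   Right-hand-side terms may be factors (categorical time, treatment-coded
#'   against the first level) or numeric (continuous time / covariates);
#'   every term is automatically expanded per response coordinate.
#' @param data long-format data.frame, one row per subject-occasion.
#' @param subject name of the subject identifier column (character, or a
#'   one-sided formula such as `~ id`).
#' @param occasion optional name of the occasion column; used for
#'   (subject, occasion) uniqueness checking.
#' @param basis an [olr_basis] over the behaviour columns; defaults to pivot
#'   coordinates in the order given on the left-hand side.
#' @param kappa closure constant of the composition (e.g. 1440 min/day); if
#'   `NULL`, the median row sum of the behaviours is used.
#' @param g_structure,e_structure `"unstructured"` (default) or
#'   `"diagonal"` covariance across coordinates for the random intercepts
#'   and residuals respectively.
#' @param method `"REML"` (default) or `"ML"`.
#' @param tolerance passed to [validate_long()].
#' @param control a [cmrlmm_control()] list.
#' @return An object of class `"cmrlmm"`; see [coef.cmrlmm()],
#'   [summary.cmrlmm()], [predict.cmrlmm()], [compositional_coef()],
#'   [joint_test()], [lrt()], [cases_bootstrap()].
#' @examples
#' d <- make_fixture("tiny", seed = 1)
#' b <- loh_basis()
#' fit <- cmrlmm(cbind(sleep, sb, lpa, mvpa) ~ occasion, data = d,
#'               subject = "id", basis = b, kappa = 1440)
#' fit
#' compositional_coef(fit)
#' @export
cmrlmm <- function(formula, data, subject, occasion = NULL, basis = NULL,
                   kappa = NULL,
                   g_structure = c("unstructured", "diagonal"),
                   e_structure = c("unstructured", "diagonal"),
                   method = c("REML", "ML"), tolerance = 0.05,
                   control = cmrlmm_control()) {
  cl <- match.call()
  g_structure <- match.arg(g_structure)
  e_structure <- match.arg(e_structure)
  method <- match.arg(method)
  if (inherits(subject, "formula")) subject <- all.vars(subject)[1L]

  lhs <- formula[[2L]]
  if (!(is.call(lhs) && identical(as.character(lhs[[1L]]), "cbind"))) {
    stop("left-hand side must be cbind(part1, part2, ...)")
  }
  parts_names <- vapply(as.list(lhs)[-1L], function(e) deparse(e), character(1))
  if (length(parts_names) < 2L) stop("need at least two behaviour columns")

  if (is.null(basis)) basis <- pivot_basis(parts_names)
  if (!identical(sort(basis$labels), sort(parts_names))) {
    stop("basis labels do not match the behaviour columns on the LHS")
  }
  parts_names <- basis$labels # basis fixes part order

  data <- as.data.frame(data)
  if (is.null(kappa)) {
    kappa <- stats::median(rowSums(data[, parts_names, drop = FALSE]))
  }
  data <- validate_long(data, parts = parts_names, subject = subject,
                        occasion = occasion, kappa = kappa,
                        tolerance = tolerance)

  rhs_terms <- stats::delete.response(stats::terms(formula, data = data))
  mf <- stats::model.frame(rhs_terms, data, na.action = stats::na.pass)
  cc <- stats::complete.cases(mf)
  if (!all(cc)) {
    message(sum(!cc), " row(s) dropped due to missing model variables")
    data <- data[cc, , drop = FALSE]
    mf <- mf[cc, , drop = FALSE]
  }
  X0 <- stats::model.matrix(rhs_terms, mf)
  qrX <- qr(X0)
  if (qrX$rank < ncol(X0)) {
    aliased <- colnames(X0)[qrX$pivot[(qrX$rank + 1L):ncol(X0)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  if (length(unique(data[[subject]])) < 2L) stop("need at least 2 subjects")

  olr_data <- compute_olr(data, basis)
  Z <- as.matrix(olr_data[, colnames(basis$contrast), drop = FALSE])

  engine <- prepare_engine(Z, X0, data[[subject]])
  res <- fit_engine(engine, g_structure, e_structure, method, control)

  fit <- structure(list(
    beta = res$beta, vcov_beta = res$vcov_beta, G = res$G, E = res$E,
    blups = res$blups, loglik = res$loglik, theta = res$theta,
    converged = res$converged, boundary = res$boundary, optim = res$optim,
    n_params = length(res$beta) + res$n_cov_params,
    n_fixed = length(res$beta), n_cov_params = res$n_cov_params,
    n_obs = engine$n_obs, n_long = engine$n_long,
    n_subjects = engine$n_subjects,
    method = method, g_structure = g_structure, e_structure = e_structure,
    basis = basis, parts = parts_names, kappa = kappa,
    formula = formula, terms = rhs_terms,
    xlevels = stats::.getXlevels(rhs_terms, mf),
    contrasts = attr(X0, "contrasts"),
    base_coefnames = colnames(X0), assign = attr(X0, "assign"),
    subject_var = subject, occasion_var = occasion,
    data = data, engine = engine, control = control, call = cl),
    class = "cmrlmm")
  fit
}

#' Refit a model on new data with the same specification
#'
#' Used internally by the cases bootstrap; exported because it is also handy
#' for sensitivity analyses.
#'
#' @param fit a fitted `"cmrlmm"`.
#' @param newdata a long-format data.frame with the same columns as the
#'   original data.
#' @param validate re-run [validate_long()] on `newdata` (default `FALSE`:
#'   bootstrap resamples are drawn from already-validated rows).
#' @return A new `"cmrlmm"` fit.
#' @export
refit <- function(fit, newdata, validate = FALSE) {
  stopifnot(inherits(fit, "cmrlmm"))
  data <- as.data.frame(newdata)
  if (validate) {
    data <- validate_long(data, parts = fit$parts, subject = fit$subject_var,
                          occasion = fit$occasion_var, kappa = fit$kappa)
  }
  mf <- stats::model.frame(fit$terms, data, na.action = stats::na.pass,
                           xlev = fit$xlevels)
  cc <- stats::complete.cases(mf)
  data <- data[cc, , drop = FALSE]
  mf <- mf[cc, , drop = FALSE]
  X0 <- stats::model.matrix(fit$terms, mf, contrasts.arg = fit$contrasts)
  olr_data <- compute_olr(data, fit$basis)
  Z <- as.matrix(olr_data[, colnames(fit$basis$contrast), drop = FALSE])
  engine <- prepare_engine(Z, X0, data[[fit$subject_var]])
  res <- fit_engine(engine, fit$g_structure, fit$e_structure, fit$method,
                    fit$control)
  out <- fit
  out$beta <- res$beta; out$vcov_beta <- res$vcov_beta
  out$G <- res$G; out$E <- res$E; out$blups <- res$blups
  out$loglik <- res$loglik; out$theta <- res$theta
  out$converged <- res$converged; out$boundary <- res$boundary
  out$optim <- res$optim
  out$n_params <- length(res$beta) + res$n_cov_params
  out$n_fixed <- length(res$beta); out$n_cov_params <- res$n_cov_params
  out$n_obs <- engine$n_obs; out$n_long <- engine$n_long
  out$n_subjects <- engine$n_subjects
  out$data <- data; out$engine <- engine
  out
}

#' Fit the unrelated-outcomes comparator model
#'
#' The same model as [cmrlmm()] with both covariance matrices constrained to
#' be diagonal: coordinates are modelled with no cross-coordinate covariance,
#' which reproduces the estimates of D-1 separate univariate fits and makes
#' back-transformed results depend on the olr basis.
#'
#' @inheritParams cmrlmm
#' @param ... passed to [cmrlmm()].
#' @export
fit_unrelated <- function(formula, data, subject, ...) {
  cmrlmm(formula, data, subject = subject,
         g_structure = "diagonal", e_structure = "diagonal", ...)
}
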