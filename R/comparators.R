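# Comparator fits: the approaches the joint model replaces. Each coordinate
# (or each raw behaviour) is fitted in its own univariate random-intercept
# mixed model, which ignores cross-coordinate covariance. Back-transformed
# results from the per-coordinate suite depend on the olr basis, and
# raw-minutes fits do not respect the constant-sum constraint.

fit_univariate_lmm <- function(y, X0, subject, method, control) {
  engine <- prepare_engine(matrix(y, ncol = 1L), X0, subject)
  res <- fit_engine(engine, "unstructured", "unstructured", method, control)
  list(beta = res$beta, se = sqrt(diag(res$vcov_beta)),
       sigma2 = res$G[1L, 1L], tau2 = res$E[1L, 1L],
       loglik = res$loglik, blups = res$blups[, 1L],
       converged = res$converged, engine = engine)
}

#' Per-coordinate univariate mixed-model suite
#'
#' Fits each olr coordinate in its own univariate random-intercept linear
#' mixed model (the "multiple models" practice). Coefficients coincide with
#' the diagonal-constrained joint fit; once back-transformed to the simplex,
#' fitted compositions from this suite depend on the olr basis, unlike the
#' full-covariance joint model.
#'
#' @inheritParams cmrlmm
#' @return An object of class `"cmrlmm_suite"` with one fit per coordinate.
#' @export
univariate_suite <- function(formula, data, subject, occasion = NULL,
                             basis = NULL, kappa = NULL,
                             method = c("REML", "ML"), tolerance = 0.05,
                             control = cmrlmm_control()) {
  method <- match.arg(method)
  if (inherits(subject, "formula")) subject <- all.vars(subject)[1L]
  lhs <- formula[[2L]]
  parts_names <- vapply(as.list(lhs)[-1L], deparse, character(1))
  if (is.null(basis)) basis <- pivot_basis(parts_names)
  parts_names <- basis$labels
  data <- as.data.frame(data)
  if (is.null(kappa)) {
    kappa <- stats::median(rowSums(data[, parts_names, drop = FALSE]))
  }
  data <- validate_long(data, parts = parts_names, subject = subject,
                        occasion = occasion, kappa = kappa,
                        tolerance = tolerance)
  rhs_terms <- stats::delete.response(stats::terms(formula, data = data))
  mf <- stats::model.frame(rhs_terms, data)
  X0 <- stats::model.matrix(rhs_terms, mf)
  olr_data <- compute_olr(data, basis)
  zn <- colnames(basis$contrast)
  fits <- lapply(zn, function(z) {
    fit_univariate_lmm(olr_data[[z]], X0, data[[subject]], method, control)
  })
  names(fits) <- zn
  structure(list(fits = fits, basis = basis, parts = parts_names,
                 kappa = kappa, data = data, X0 = X0, subject_var = subject,
                 terms = rhs_terms, method = method, type = "olr"),
            class = "cmrlmm_suite")
}

#' Per-behaviour raw-minutes mixed-model suite
#'
#' Fits each behaviour's raw duration (min/day) in its own univariate
#' random-intercept mixed model, ignoring the compositional structure
#' entirely. Fitted durations summed over behaviours need not equal the
#' day length, illustrating the constant-sum violation of this common
#' practice.
#'
#' @inheritParams univariate_suite
#' @param parts behaviour column names.
#' @return An object of class `"cmrlmm_suite"` (`type = "raw"`).
#' @export
raw_minutes_suite <- function(formula, data, subject, occasion = NULL,
                              parts = NULL, kappa = NULL,
                              method = c("REML", "ML"), tolerance = 0.05,
                              control = cmrlmm_control()) {
  method <- match.arg(method)
  if (inherits(subject, "formula")) subject <- all.vars(subject)[1L]
  if (is.null(parts)) {
    parts <- vapply(as.list(formula[[2L]])[-1L], deparse, character(1))
  }
  data <- as.data.frame(data)
  if (is.null(kappa)) {
    kappa <- stats::median(rowSums(data[, parts, drop = FALSE]))
  }
  data <- validate_long(data, parts = parts, subject = subject,
                        occasion = occasion, kappa = kappa,
                        tolerance = tolerance)
  rhs_terms <- stats::delete.response(stats::terms(formula, data = data))
  mf <- stats::model.frame(rhs_terms, data)
  X0 <- stats::model.matrix(rhs_terms, mf)
  fits <- lapply(parts, function(p) {
    fit_univariate_lmm(data[[p]], X0, data[[subject]], method, control)
  })
  names(fits) <- parts
  structure(list(fits = fits, basis = NULL, parts = parts, kappa = kappa,
                 data = data, X0 = X0, subject_var = subject,
                 terms = rhs_terms, method = method, type = "raw"),
            class = "cmrlmm_suite")
}

#' @export
print.cmrlmm_suite <- function(x, digits = 4, ...) {
  cat(sprintf("suite of %d univariate mixed models (%s responses)\n",
              length(x$fits), x$type))
  B <- suite_coef(x)
  print(round(B, digits))
  invisible(x)
}

#' Coefficients of a comparator suite, term by response
#'
#' @param suite a `"cmrlmm_suite"`.
#' @export
suite_coef <- function(suite) {
  B <- vapply(suite$fits, function(f) unname(f$beta),
              numeric(ncol(suite$X0)))
  rownames(B) <- colnames(suite$X0)
  B
}

#' Fitted responses of a comparator suite
#'
#' @param suite a `"cmrlmm_suite"`.
#' @param level `"conditional"` (including subject BLUPs) or `"marginal"`.
#' @return For an olr suite, the fitted coordinate matrix; for a raw suite,
#'   the fitted minutes per behaviour (rows need not sum to `kappa`).
#' @export
suite_fitted <- function(suite, level = c("conditional", "marginal")) {
  level <- match.arg(level)
  sub <- factor(suite$data[[suite$subject_var]])
  out <- vapply(suite$fits, function(f) {
    eta <- drop(suite$X0 %*% f$beta)
    if (level == "conditional") eta <- eta + f$blups[as.character(sub)]
    eta
  }, numeric(nrow(suite$X0)))
  colnames(out) <- names(suite$fits)
  out
}

#' Back-transformed fitted compositions of an olr suite
#'
#' Combines the independently fitted coordinates of a [univariate_suite()]
#' and maps them to the simplex. Because the coordinates were fitted with
#' no cross-coordinate covariance, these compositions change when a
#' different olr basis is used - the defect the joint model removes.
#'
#' @inheritParams suite_fitted
#' @export
suite_fitted_composition <- function(suite,
                                     level = c("conditional", "marginal")) {
  if (suite$type != "olr") stop("only olr suites map back to compositions")
  Zf <- suite_fitted(suite, level)
  comp <- exp(Zf %*% t(suite$basis$contrast))
  comp <- comp * (suite$kappa / rowSums(comp))
  colnames(comp) <- suite$parts
  comp
}

#' Constant-sum violation of a raw-minutes suite
#'
#' Largest absolute deviation of fitted behaviour sums from `kappa` across
#' subject-occasions. Subject-level (conditional) predictions violate the
#' constraint because each behaviour's random intercept is shrunken by its
#' own variance ratio; marginal predictions also violate it whenever the
#' data are unbalanced (on a perfectly balanced design, per-behaviour GLS
#' coincides with OLS, whose fitted values happen to sum exactly - a
#' knife-edge special case, not a property of the approach).
#'
#' @param suite a raw `"cmrlmm_suite"`.
#' @param level passed to [suite_fitted()].
#' @return The largest absolute deviation of fitted behaviour sums from
#'   `kappa` across subject-occasions.
#' @export
constant_sum_violation <- function(suite, level = "conditional") {
  if (suite$type != "raw") stop("only raw-minutes suites can violate the sum")
  max(abs(rowSums(suite_fitted(suite, level)) - suite$kappa))
}
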