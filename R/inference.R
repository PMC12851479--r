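#' Joint multivariate test on a fixed-effect term block
#'
#' Tests all coordinates' coefficients of one base design term jointly:
#' `F = (L b)' (L V L')^{-1} (L b) / rank(L)` with `V` the coefficient
#' covariance. For blocks spanning every coordinate of a term this statistic
#' is invariant to the olr basis used to construct the coordinates, unlike
#' per-coordinate tests. The denominator df uses the between-within counting
#' rule (see [den_df()]); a Wald chi-square variant (`rank(L) * F` against
#' `chi^2_rank(L)`) is available via `chisq = TRUE`.
#'
#' @param fit a fitted `"cmrlmm"`.
#' @param term a base term label: `"(Intercept)"` (the coordinate intercept
#'   block, printed as `Z`) or one of the right-hand-side term labels.
#' @param chisq report the chi-square form instead of the F form.
#' @return A one-row data.frame: term, statistic, num_df, den_df, p_value.
#' @export
joint_test <- function(fit, term, chisq = FALSE) {
  stopifnot(inherits(fit, "cmrlmm"))
  labs <- c("(Intercept)", attr(fit$terms, "term.labels"))
  if (!(term %in% labs)) {
    stop("unknown term '", term, "'; available: ", paste(labs, collapse = ", "))
  }
  base_assign <- fit$assign # 0 = intercept
  want <- match(term, labs) - 1L
  q <- length(fit$base_coefnames)
  R <- length(fit$engine$coord_names)
  cols <- which(rep(base_assign, R) == want)
  b <- fit$beta[cols]
  V <- fit$vcov_beta[cols, cols, drop = FALSE]
  cV <- tryCatch(chol(V), error = function(e)
    stop("tested block has a rank-deficient covariance"))
  r <- length(cols)
  wald <- sum(backsolve(cV, b, transpose = TRUE)^2)
  Fstat <- wald / r
  df2 <- den_df(fit)
  label <- if (term == "(Intercept)") "Z" else paste0("Z:", term)
  if (chisq) {
    data.frame(term = label, statistic = wald, num_df = r, den_df = Inf,
               p_value = stats::pchisq(wald, r, lower.tail = FALSE),
               row.names = NULL)
  } else {
    data.frame(term = label, statistic = Fstat, num_df = r, den_df = df2,
               p_value = stats::pf(Fstat, r, df2, lower.tail = FALSE),
               row.names = NULL)
  }
}

#' Joint tests for every fixed-effect term
#'
#' @inheritParams joint_test
#' @return Data.frame with one row per term (intercept block first).
#' @export
joint_tests <- function(fit, chisq = FALSE) {
  labs <- c("(Intercept)", attr(fit$terms, "term.labels"))
  do.call(rbind, lapply(labs, function(tm) joint_test(fit, tm, chisq = chisq)))
}

#' Likelihood-ratio test between nested fits
#'
#' `LR = 2 (logLik(full) - logLik(reduced))` against a chi-square with df
#' equal to the parameter-count difference. Both fits must use the same
#' estimation method; under REML the fixed effects must be identical, so the
#' test compares covariance structures only (e.g. unstructured vs diagonal G
#' and E, where the constrained correlations of zero are interior points of
#' the parameter space and the chi-square reference applies; variance
#' components on the boundary would instead need a mixture reference).
#'
#' @param full,reduced fitted `"cmrlmm"` objects, `reduced` nested in
#'   `full`.
#' @return A one-row data.frame: statistic, df, p_value.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "cmrlmm"), inherits(reduced, "cmrlmm"))
  if (full$method != reduced$method) {
    stop("fits use different estimation methods (", full$method, " vs ",
         reduced$method, ")")
  }
  if (full$method == "REML" &&
      !identical(names(full$beta), names(reduced$beta))) {
    stop("REML likelihoods are not comparable across different fixed effects; ",
         "refit with method = 'ML'")
  }
  df <- full$n_params - reduced$n_params
  if (df < 0) stop("'reduced' has more parameters than 'full'; swap arguments")
  stat <- 2 * (full$loglik - reduced$loglik)
  if (df == 0) {
    return(data.frame(statistic = max(stat, 0), df = 0L, p_value = 1))
  }
  if (stat < -1e-6) {
    warning("negative LR statistic (", format(stat), "); models may not be nested")
  }
  stat <- max(stat, 0)
  data.frame(statistic = stat, df = df,
             p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' @export
anova.cmrlmm <- function(object, object2, ...) {
  if (missing(object2)) return(joint_tests(object))
  fits <- list(object, object2)
  np <- vapply(fits, function(f) f$n_params, numeric(1))
  o <- order(np, decreasing = TRUE)
  full <- fits[[o[1L]]]; reduced <- fits[[o[2L]]]
  tst <- lrt(full, reduced)
  out <- data.frame(
    model = c("full", "reduced"),
    n_params = c(full$n_params, reduced$n_params),
    AIC = c(stats::AIC(full), stats::AIC(reduced)),
    BIC = c(stats::BIC(full), stats::BIC(reduced)),
    logLik = c(full$loglik, reduced$loglik),
    L_ratio = c(tst$statistic, NA),
    df = c(tst$df, NA),
    p_value = c(tst$p_value, NA))
  out
}
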