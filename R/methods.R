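#' @export
print.cmrlmm <- function(x, digits = 4, ...) {
  cat("Compositional multivariate-response linear mixed model\n")
  cat(sprintf("  parts: %s (kappa = %g); basis: %s\n",
              paste(x$parts, collapse = ", "), x$kappa, x$basis$provenance))
  cat(sprintf("  %d subjects, %d subject-occasions, %d stacked observations\n",
              x$n_subjects, x$n_long, x$n_obs))
  cat(sprintf("  method: %s; G: %s; E: %s; logLik: %.3f (%d parameters)\n",
              x$method, x$g_structure, x$e_structure, x$loglik, x$n_params))
  if (!x$converged) cat("  WARNING: convergence criteria not met\n")
  cat("\nFixed effects (per coordinate):\n")
  print(round(coef_matrix(x), digits))
  invisible(x)
}

#' Fixed effects arranged as a term-by-coordinate matrix
#'
#' @param object a fitted `"cmrlmm"`.
#' @return Matrix with one row per base design term and one column per olr
#'   coordinate.
#' @export
coef_matrix <- function(object) {
  q <- length(object$base_coefnames)
  R <- length(object$engine$coord_names)
  matrix(object$beta, nrow = q, ncol = R,
         dimnames = list(object$base_coefnames, object$engine$coord_names))
}

#' @export
coef.cmrlmm <- function(object, ...) object$beta

#' @export
vcov.cmrlmm <- function(object, ...) object$vcov_beta

#' @export
logLik.cmrlmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params,
            nobs = object$n_obs, class = "logLik")
}

#' @export
nobs.cmrlmm <- function(object, ...) object$n_obs

#' Random-intercept predictions (BLUPs)
#'
#' @param object a fitted `"cmrlmm"`.
#' @param ... unused.
#' @return Matrix of per-subject best linear unbiased predictors, one row
#'   per subject and one column per olr coordinate.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @rdname ranef
#' @export
ranef.cmrlmm <- function(object, ...) object$blups

#' Denominator degrees of freedom (between-within counting rule)
#'
#' All fixed effects in the stacked layout are interacted with the response
#' index and therefore vary within subjects, so a single inner-level
#' denominator df applies: stacked observations minus subjects minus the
#' number of fixed effects. This is a counting approximation, not a
#' Satterthwaite or Kenward-Roger adjustment.
#'
#' @param object a fitted `"cmrlmm"`.
#' @export
den_df <- function(object) {
  max(object$n_obs - object$n_subjects - object$n_fixed, 1L)
}

#' Per-coefficient Wald tests
#'
#' @param object a fitted `"cmrlmm"`.
#' @return Data frame with estimate, standard error, t statistic,
#'   denominator df and two-sided p-value per stacked coefficient. Joint
#'   tests over whole term blocks ([joint_test()]) are preferable to reading
#'   many per-coordinate tests, whose multiplicity inflates type-I error.
#' @export
coef_tests <- function(object) {
  stopifnot(inherits(object, "cmrlmm"))
  if (!object$converged) {
    warning("model did not converge; tests may be unreliable")
  }
  se <- sqrt(diag(object$vcov_beta))
  t <- object$beta / se
  df <- den_df(object)
  data.frame(estimate = object$beta, se = se, t = t, df = df,
             p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' @export
summary.cmrlmm <- function(object, ...) {
  out <- list(fit = object, tests = coef_tests(object),
              joint = joint_tests(object),
              aic = stats::AIC(object), bic = stats::BIC(object))
  class(out) <- "summary.cmrlmm"
  out
}

#' @export
print.summary.cmrlmm <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("\nAIC: %.1f  BIC: %.1f  (BIC n = stacked observations)\n",
              x$aic, x$bic))
  cat("\nRandom-intercept covariance G (between subjects):\n")
  print(round(x$fit$G, digits))
  cat("\nResidual covariance E (within subject-occasion):\n")
  print(round(x$fit$E, digits))
  cat("\nPer-coefficient tests:\n")
  print(round(x$tests, digits))
  cat("\nJoint multivariate F tests (prefer these to per-coordinate tests):\n")
  print(x$joint, digits = digits)
  invisible(x)
}

#' @export
fitted.cmrlmm <- function(object, level = c("marginal", "conditional"), ...) {
  level <- match.arg(level)
  engine <- object$engine
  eta <- matrix(drop(engine$X %*% object$beta), ncol = engine$R, byrow = TRUE)
  if (level == "conditional") {
    eta <- eta + object$blups[as.integer(engine$subject), , drop = FALSE]
  }
  out <- matrix(NA_real_, engine$n_long, engine$R,
                dimnames = list(NULL, engine$coord_names))
  out[engine$order, ] <- eta
  out
}

#' @export
residuals.cmrlmm <- function(object, level = c("conditional", "marginal"), ...) {
  level <- match.arg(level)
  engine <- object$engine
  Zl <- matrix(NA_real_, engine$n_long, engine$R,
               dimnames = list(NULL, engine$coord_names))
  Zl[engine$order, ] <- engine$Z
  Zl - fitted(object, level = level)
}

#' Predict olr coordinates or compositions from a fitted model
#'
#' @param object a fitted `"cmrlmm"`.
#' @param newdata data.frame of covariate settings; defaults to the model
#'   data. Factor columns must use known levels.
#' @param type `"olr"` for coordinate predictions (matrix, one column per
#'   coordinate) or `"composition"` for back-transformed parts (matrix whose
#'   rows each sum to `kappa`).
#' @param include_blups add each row's subject random-intercept prediction;
#'   requires the subject column in `newdata` with subjects seen at fit time.
#' @param kappa closure constant for `type = "composition"`; defaults to the
#'   fit's kappa.
#' @param ... unused.
#' @export
predict.cmrlmm <- function(object, newdata = NULL,
                           type = c("olr", "composition"),
                           include_blups = FALSE, kappa = object$kappa, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  mf <- stats::model.frame(object$terms, newdata, na.action = stats::na.fail,
                           xlev = object$xlevels)
  X0 <- stats::model.matrix(object$terms, mf, contrasts.arg = object$contrasts)
  eta <- X0 %*% coef_matrix(object)
  if (include_blups) {
    if (!(object$subject_var %in% names(newdata))) {
      stop("'newdata' must contain the subject column when include_blups = TRUE")
    }
    ids <- as.character(newdata[[object$subject_var]])
    unknown <- setdiff(ids, rownames(object$blups))
    if (length(unknown) > 0L) {
      stop("unknown subject(s): ", paste(unique(unknown), collapse = ", "))
    }
    eta <- eta + object$blups[ids, , drop = FALSE]
  }
  rownames(eta) <- NULL
  if (type == "olr") return(eta)
  comp <- t(apply(eta, 1L, function(z) parts(olr_inv(z, object$basis, kappa))))
  colnames(comp) <- object$parts
  comp
}

#' Predict a single composition
#'
#' Convenience wrapper around [predict.cmrlmm()] returning a
#' `"composition"` for a one-row covariate setting.
#'
#' @inheritParams predict.cmrlmm
#' @export
predict_composition <- function(object, newdata, include_blups = FALSE,
                                kappa = object$kappa) {
  comp <- predict(object, newdata = newdata, type = "composition",
                  include_blups = include_blups, kappa = kappa)
  if (nrow(comp) == 1L) {
    composition(comp[1L, ], kappa = kappa, labels = object$parts)
  } else {
    comp
  }
}

#' Simulate response datasets from a fitted model
#'
#' Parametric simulation at the fitted parameters: new random intercepts and
#' residuals are drawn for the observed design, and behaviours are rebuilt by
#' the inverse olr transform.
#'
#' @param object a fitted `"cmrlmm"`.
#' @param nsim number of simulated datasets.
#' @param seed optional seed, handled as in [stats::simulate()].
#' @param ... unused.
#' @return A list of `nsim` long-format data.frames shaped like the model
#'   data with behaviours replaced by simulated values.
#' @export
simulate.cmrlmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  engine <- object$engine
  R <- engine$R
  eta <- predict(object, newdata = object$data, type = "olr")
  sub <- factor(object$data[[object$subject_var]])
  cG <- chol(object$G)
  cE <- chol(object$E)
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    b <- matrix(stats::rnorm(nlevels(sub) * R), ncol = R) %*% cG
    eps <- matrix(stats::rnorm(nrow(eta) * R), ncol = R) %*% cE
    z <- eta + b[as.integer(sub), , drop = FALSE] + eps
    d <- object$data
    comp <- t(apply(z, 1L, function(zz)
      parts(olr_inv(zz, object$basis, object$kappa))))
    d[, object$parts] <- comp
    out[[k]] <- d
  }
  out
}

#' Plot predicted compositions across a factor
#'
#' Stacked-bar display of the predicted composition at each level of a
#' factor covariate (typically the occasion), other covariates held at
#' reference/mean values as in [reference_grid()].
#'
#' @param x a fitted `"cmrlmm"`.
#' @param by name of a factor covariate; defaults to the first factor in the
#'   model.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.cmrlmm <- function(x, by = NULL, ...) {
  grid <- reference_grid(x, by = by)
  comp <- predict(x, newdata = grid$data, type = "composition")
  graphics::barplot(t(comp), names.arg = grid$levels, legend.text = x$parts,
                    ylab = sprintf("parts (sum %g)", x$kappa),
                    xlab = grid$by, ...)
  invisible(comp)
}

#' Reference covariate grid for "average participant" predictions
#'
#' One row per level of `by`; all other numeric covariates are set to their
#' sample mean and other factors to their reference (first) level. The
#' convention is stated explicitly because "average participant" is
#' ambiguous between mean covariates and reference categories.
#'
#' @param object a fitted `"cmrlmm"`.
#' @param by factor covariate to vary; defaults to the first factor term.
#' @export
reference_grid <- function(object, by = NULL) {
  vars <- all.vars(stats::delete.response(object$terms))
  data <- object$data
  if (is.null(by)) {
    isfac <- vapply(vars, function(v) is.factor(data[[v]]) ||
                      is.character(data[[v]]), logical(1))
    if (!any(isfac)) stop("no factor covariate to vary; give 'by'")
    by <- vars[isfac][1L]
  }
  lev <- if (!is.null(object$xlevels[[by]])) object$xlevels[[by]] else
    levels(factor(data[[by]]))
  grid <- data.frame(row.names = seq_along(lev))
  grid[[by]] <- factor(lev, levels = lev)
  for (v in setdiff(vars, by)) {
    if (is.numeric(data[[v]])) {
      grid[[v]] <- mean(data[[v]])
    } else {
      l0 <- object$xlevels[[v]]
      if (is.null(l0)) l0 <- levels(factor(data[[v]]))
      grid[[v]] <- factor(l0[1L], levels = l0)
    }
  }
  list(data = grid, by = by, levels = lev,
       convention = "numeric covariates at sample mean, factors at reference level")
}
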