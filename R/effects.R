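#' Back-transform fixed effects into compositional coefficients
#'
#' Each base design term has one coefficient per olr coordinate; applying
#' the inverse olr to that coordinate vector gives its compositional
#' representation. The intercept block becomes the baseline composition
#' (closed to `kappa`, e.g. min/day at the reference covariate setting);
#' every other block becomes a perturbation vector closed to 1, read against
#' the neutral element `[1/D, ..., 1/D]`: parts above `1/D` gain time
#' relative to the baseline, parts below lose it. For full-covariance fits
#' these compositional coefficients are invariant to the olr basis.
#'
#' @param fit a fitted `"cmrlmm"`.
#' @return An object of class `"cmrlmm_ccoef"`: a data.frame with one row
#'   per term (columns: term, role, one column per part). Effect rows sum to
#'   1, the intercept row to `kappa`.
#' @export
compositional_coef <- function(fit) {
  stopifnot(inherits(fit, "cmrlmm"))
  B <- coef_matrix(fit) # q x R
  terms <- rownames(B)
  D <- length(fit$parts)
  out <- data.frame(term = terms,
                    role = ifelse(terms == "(Intercept)", "baseline",
                                  "perturbation"),
                    stringsAsFactors = FALSE)
  M <- t(vapply(seq_along(terms), function(k) {
    kap <- if (terms[k] == "(Intercept)") fit$kappa else 1
    parts(olr_inv(B[k, ], fit$basis, kappa = kap))
  }, numeric(D)))
  colnames(M) <- fit$parts
  out <- cbind(out, as.data.frame(M))
  attr(out, "kappa") <- fit$kappa
  class(out) <- c("cmrlmm_ccoef", "data.frame")
  out
}

#' @export
print.cmrlmm_ccoef <- function(x, digits = 3, ...) {
  cat("Compositional coefficients\n")
  cat(sprintf("  baseline row closed to kappa = %g; perturbation rows closed to 1\n",
              attr(x, "kappa")))
  cat("  (perturbation parts > 1/D reallocate time toward that part)\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(col) round(col, digits))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Log-ratio difference between two compositions
#'
#' `clr(a) - clr(b)`, the clr coordinates of the perturbation difference
#' `a (-) b`. Components sum to zero; a component above zero means part is
#' relatively higher in `a` than in `b`. This is the display used to compare
#' predicted compositions between conditions (e.g. in-school minus holiday
#' timepoints).
#'
#' @param a,b `"composition"` objects over the same parts.
#' @return Named numeric vector of length D summing to 0.
#' @export
logratio_difference <- function(a, b) {
  stopifnot(inherits(a, "composition"), inherits(b, "composition"))
  check_same_parts(a, b)
  clr(a) - clr(b)
}

#' Deviations of a perturbation coefficient from the neutral element
#'
#' For an effect-role compositional coefficient, reports each part's signed
#' deviation from `1/D` with a direction label: positive deviations mean
#' time is reallocated toward that part at the corresponding covariate
#' setting, negative away from it.
#'
#' @param coef either a one-row perturbation slice of a
#'   [compositional_coef()] table, or a `"composition"` closed to 1.
#' @return Data.frame with part, value, deviation and direction columns.
#' @export
perturbation_vs_neutral <- function(coef) {
  if (inherits(coef, "cmrlmm_ccoef")) {
    if (nrow(coef) != 1L) stop("give a single coefficient row")
    if (coef$role != "perturbation") {
      stop("the baseline (intercept) row is a composition, not a perturbation")
    }
    v <- as.numeric(coef[1L, -(1:2)])
    names(v) <- names(coef)[-(1:2)]
  } else if (inherits(coef, "composition")) {
    v <- parts(clo(coef, kappa = 1))
  } else {
    stop("'coef' must be a compositional coefficient row or a composition")
  }
  D <- length(v)
  dev <- v - 1 / D
  data.frame(part = names(v), value = v, deviation = dev,
             direction = ifelse(abs(dev) < .Machine$double.eps^0.5, "neutral",
                                ifelse(dev > 0, "toward", "away")),
             row.names = NULL)
}
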