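#' Construct a composition
#'
#' A composition is a vector of strictly positive parts carrying only relative
#' information, e.g. minutes per day spent in sleep, sedentary behaviour (SB),
#' light physical activity (LPA) and moderate-to-vigorous physical activity
#' (MVPA). The constructor closes the raw parts so that they sum to the
#' closure constant `kappa` (1440 for min/day, 24 for h/day, 1 for
#' proportions). Internally parts are stored as proportions of the whole;
#' `kappa` is metadata applied when parts are extracted or printed, so that
#' all simplex operations are automatically scale invariant.
#'
#' Parts equal to zero are a hard error: log-ratio methods are undefined at
#' zero and no imputation is attempted here. See the zero-replacement
#' literature (e.g. multiplicative or model-based replacement) for ways to
#' treat genuine or rounded zeros before analysis.
#'
#' @param x numeric vector of strictly positive parts.
#' @param kappa positive closure constant the parts should sum to on output.
#' @param labels optional character vector of part names; defaults to
#'   `names(x)` or `x1, x2, ...`.
#' @return An object of class `"composition"`.
#' @examples
#' composition(c(sleep = 8, sb = 8, lpa = 4, mvpa = 4), kappa = 1440)
#' @export
composition <- function(x, kappa = 1, labels = NULL) {
  if (is.null(labels)) labels <- names(x)
  x <- as.numeric(x)
  if (is.null(labels)) labels <- paste0("x", seq_along(x))
  if (length(labels) != length(x)) {
    stop("'labels' must have one entry per part")
  }
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0) {
    stop("'kappa' must be a single positive number")
  }
  if (any(!is.finite(x))) {
    stop("non-finite part(s): ", paste(labels[!is.finite(x)], collapse = ", "))
  }
  bad <- x <= 0
  if (any(bad)) {
    stop("part(s) not strictly positive: ",
         paste(labels[bad], collapse = ", "),
         ". Zero parts are not supported; apply a zero-replacement method ",
         "before constructing compositions.")
  }
  p <- x / sum(x)
  names(p) <- labels
  structure(p, kappa = kappa, class = "composition")
}

#' Close a positive vector to a constant
#'
#' The closure operation rescales a strictly positive vector so its parts sum
#' to `kappa`; this is the canonical projection of a positive vector onto the
#' simplex.
#'
#' @inheritParams composition
#' @return A `"composition"` closed to `kappa`.
#' @examples
#' clo(c(8, 8, 4, 4), kappa = 1440)
#' @export
clo <- function(x, kappa = 1, labels = NULL) {
  if (inherits(x, "composition")) {
    return(composition(unclass(x), kappa = kappa, labels = names(x)))
  }
  composition(x, kappa = kappa, labels = labels)
}

#' @export
print.composition <- function(x, digits = 4, ...) {
  k <- attr(x, "kappa")
  cat(sprintf("composition (%d parts, closed to %g)\n", length(x), k))
  print(round(parts(x), digits))
  invisible(x)
}

#' Extract the parts of a composition on its closure scale
#'
#' @param x a `"composition"`.
#' @return Named numeric vector summing to `kappa(x)`.
#' @export
parts <- function(x) {
  stopifnot(inherits(x, "composition"))
  out <- unclass(x) * attr(x, "kappa")
  attr(out, "kappa") <- NULL
  out
}

#' @rdname parts
#' @export
kappa_of <- function(x) {
  stopifnot(inherits(x, "composition"))
  attr(x, "kappa")
}

#' @export
as.numeric.composition <- function(x, ...) parts(x)

check_same_parts <- function(x, y) {
  if (length(x) != length(y)) {
    stop("compositions have different numbers of parts")
  }
  if (!identical(names(x), names(y))) {
    stop("compositions have different part labels: ",
         paste(names(x), collapse = ","), " vs ",
         paste(names(y), collapse = ","))
  }
  invisible(TRUE)
}

#' Simplex operations: perturbation, powering, inverse, neutral element
#'
#' Perturbation `x (+) y = C[x1 y1, ..., xD yD]` is the simplex analogue of
#' addition; powering `alpha (.) x = C[x1^alpha, ..., xD^alpha]` the analogue
#' of scalar multiplication. The neutral element is the equal-parts
#' composition `[kappa/D, ..., kappa/D]`, and the perturbation-inverse of `x`
#' is `C[1/x1, ..., 1/xD]`, so `perturb(x, cinv(x))` is neutral. The result
#' keeps the closure constant of `x`.
#'
#' @param x,y `"composition"` objects over the same parts.
#' @param alpha a single finite real.
#' @param D number of parts.
#' @param kappa closure constant for the result.
#' @param labels optional part names for [cneutral()].
#' @return A `"composition"`.
#' @examples
#' x <- composition(c(584, 483, 294, 79), kappa = 1440)
#' perturb(x, cinv(x))          # neutral element
#' cpower(2, x)
#' @export
perturb <- function(x, y) {
  stopifnot(inherits(x, "composition"), inherits(y, "composition"))
  check_same_parts(x, y)
  composition(unclass(x) * unclass(y), kappa = attr(x, "kappa"),
              labels = names(x))
}

#' @rdname perturb
#' @export
cpower <- function(alpha, x) {
  stopifnot(inherits(x, "composition"))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha)) {
    stop("'alpha' must be a single finite number")
  }
  composition(unclass(x)^alpha, kappa = attr(x, "kappa"), labels = names(x))
}

#' @rdname perturb
#' @export
cinv <- function(x) {
  stopifnot(inherits(x, "composition"))
  composition(1 / unclass(x), kappa = attr(x, "kappa"), labels = names(x))
}

#' @rdname perturb
#' @export
cneutral <- function(D, kappa = 1, labels = NULL) {
  composition(rep(1, D), kappa = kappa, labels = labels)
}

#' Centred log-ratio transform
#'
#' `clr(x) = log(x / g(x))` with `g` the geometric mean; the result sums to
#' zero. The clr is used here for diagnostics and for log-ratio differences
#' between compositions, not as a modelling coordinate system (its zero-sum
#' constraint makes it singular in regression).
#'
#' @param x a `"composition"`.
#' @return Named numeric vector of length `D` summing to 0.
#' @export
clr <- function(x) {
  stopifnot(inherits(x, "composition"))
  lx <- log(unclass(x))
  out <- lx - mean(lx)
  names(out) <- names(x)
  attr(out, "kappa") <- NULL
  out
}

#' @method all.equal composition
#' @export
all.equal.composition <- function(target, current, ...) {
  if (!inherits(current, "composition")) return("'current' is not a composition")
  check_same_parts(target, current)
  all.equal(unclass(target), unclass(current),
            check.attributes = FALSE, ...)
}
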