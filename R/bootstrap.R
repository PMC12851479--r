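#' Subject-level cases bootstrap
#'
#' Non-parametric bootstrap for multilevel data: whole subjects (level-2
#' units) are resampled with replacement, each resampled subject keeping all
#' its occasions and receiving a fresh identifier so duplicates act as
#' distinct grouping units; the model is refitted on each resample and a
#' user-supplied scalar- or vector-valued quantity of the fit is recorded.
#' Percentile intervals are computed from the converged replicates.
#'
#' Reproducibility: the master `seed` spawns one sub-seed per replicate, so
#' the result is a pure function of (data, specification, quantity, B,
#' seed) and is unchanged by the order in which replicates are run.
#'
#' @param fit a fitted `"cmrlmm"`.
#' @param quantity function of a fit returning a numeric vector, e.g.
#'   `function(f) parts(predict_composition(f, newdata))`; defaults to the
#'   fixed-effect vector.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed master integer seed.
#' @param level nominal coverage of the percentile interval, in (0, 1).
#' @return An object of class `"cmrlmm_boot"`: point estimate, replicate
#'   matrix (failed replicates as `NA` rows), lower/upper percentile
#'   bounds, the failure count, and an `unreliable` flag raised when more
#'   than 5% of replicates failed. Per-dimension intervals are marginal,
#'   not joint, and the vector of interval endpoints need not itself be a
#'   composition.
#' @export
cases_bootstrap <- function(fit, quantity = function(f) coef(f),
                            B = 1000L, seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "cmrlmm"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("'level' must be a single number strictly between 0 and 1")
  }
  point <- quantity(fit)
  len <- length(point)
  data <- fit$data
  sub_col <- fit$subject_var
  ids <- unique(as.character(data[[sub_col]]))
  rows_of <- split(seq_len(nrow(data)), as.character(data[[sub_col]]))
  N <- length(ids)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, B)
  reps <- matrix(NA_real_, B, len)
  colnames(reps) <- names(point)
  n_failed <- 0L
  for (b in seq_len(B)) {
    set.seed(sub_seeds[b])
    pick <- sample(ids, N, replace = TRUE)
    idx <- unlist(rows_of[pick], use.names = FALSE)
    newdata <- data[idx, , drop = FALSE]
    newdata[[sub_col]] <- rep(paste0(pick, ".", seq_along(pick)),
                              vapply(rows_of[pick], length, integer(1)))
    val <- tryCatch({
      fb <- suppressWarnings(refit(fit, newdata))
      if (!fb$converged) NULL else quantity(fb)
    }, error = function(e) NULL)
    if (is.null(val) || length(val) != len || any(!is.finite(val))) {
      n_failed <- n_failed + 1L
    } else {
      reps[b, ] <- val
    }
  }
  ok <- stats::complete.cases(reps)
  ci <- percentile_interval(reps[ok, , drop = FALSE], level)
  unreliable <- n_failed > 0.05 * B
  if (unreliable) {
    warning(sprintf("%d of %d bootstrap replicates failed; intervals flagged unreliable",
                    n_failed, B))
  }
  structure(list(point = point, replicates = reps, lower = ci[1L, ],
                 upper = ci[2L, ], level = level, B = B, seed = seed,
                 n_failed = n_failed, unreliable = unreliable),
            class = "cmrlmm_boot")
}

#' @export
print.cmrlmm_boot <- function(x, digits = 4, ...) {
  cat(sprintf("cases bootstrap: B = %d, %d failed, %g%% percentile intervals%s\n",
              x$B, x$n_failed, 100 * x$level,
              if (x$unreliable) " (UNRELIABLE: >5% failures)" else ""))
  print(round(data.frame(estimate = x$point, lower = x$lower,
                         upper = x$upper), digits))
  invisible(x)
}

#' Percentile interval of bootstrap replicates
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2` per
#' column, using the type-7 quantile convention (the R default).
#'
#' @param replicates numeric matrix (replicates in rows) or vector.
#' @param level nominal coverage in (0, 1).
#' @return A 2-row matrix (`lower`, `upper`).
#' @export
percentile_interval <- function(replicates, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("'level' must be strictly between 0 and 1")
  }
  if (is.vector(replicates)) replicates <- matrix(replicates, ncol = 1L)
  if (nrow(replicates) < 2L) {
    stop("need at least 2 converged replicates for an interval")
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- apply(replicates, 2L, stats::quantile, probs = probs, type = 7,
               names = FALSE)
  rownames(out) <- c("lower", "upper")
  out
}
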