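#' Validate a long-format compositional dataset
#'
#' Checks one-row-per-subject-per-occasion long data with D strictly positive
#' behaviour columns. Rows whose behaviour sum deviates from `kappa` by at
#' most `tolerance` (relative) are re-closed to `kappa` with a warning; rows
#' deviating more, rows with non-positive or non-finite behaviours, and
#' duplicated (subject, occasion) pairs are rejected with an error naming the
#' offending rows. Missing occasions are allowed (unbalanced designs are
#' handled downstream); no imputation of any kind is performed.
#'
#' @param data a data.frame in long format.
#' @param parts character vector of behaviour column names (defines part
#'   order).
#' @param subject name of the subject identifier column.
#' @param occasion name of the occasion column (categorical timepoints or
#'   continuous times); optional but required for uniqueness checking and for
#'   the cases bootstrap.
#' @param kappa closure constant the behaviours should sum to (e.g. 1440).
#' @param tolerance maximum relative deviation of a row sum from `kappa`
#'   before the row is rejected rather than re-closed. Default 0.05.
#' @return The data with behaviour columns re-closed to `kappa`; a summary of
#'   cleaning actions is attached as attribute `"validation_report"`.
#' @export
validate_long <- function(data, parts, subject, occasion = NULL,
                          kappa = 1440, tolerance = 0.05) {
  data <- as.data.frame(data)
  needed <- c(parts, subject, occasion)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!is.null(occasion)) {
    key <- paste(data[[subject]], data[[occasion]], sep = "\r")
    if (anyDuplicated(key)) {
      dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
      stop("duplicate (subject, occasion) pairs in rows: ",
           paste(utils::head(dup, 10L), collapse = ", "))
    }
  }
  B <- as.matrix(data[, parts, drop = FALSE])
  if (any(!is.finite(B))) {
    bad <- which(apply(!is.finite(B), 1L, any))
    stop("non-finite behaviour values in rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  if (any(B <= 0)) {
    idx <- which(B <= 0, arr.ind = TRUE)
    stop("zero or negative behaviour values (zeros are not supported; ",
         "see the zero-replacement literature): ",
         paste(sprintf("row %d part '%s'", idx[, 1L], parts[idx[, 2L]])[
           seq_len(min(10L, nrow(idx)))], collapse = "; "))
  }
  s <- rowSums(B)
  reldev <- abs(s - kappa) / kappa
  if (any(reldev > tolerance)) {
    bad <- which(reldev > tolerance)
    stop(sprintf("row sums deviate from kappa = %g by more than %g%%: rows %s",
                 kappa, 100 * tolerance,
                 paste(utils::head(bad, 10L), collapse = ", ")))
  }
  reclosed <- which(abs(s - kappa) > 1e-9 * kappa)
  if (length(reclosed) > 0L) {
    warning(sprintf("%d row(s) re-closed to kappa = %g (max relative deviation %.3g)",
                    length(reclosed), kappa, max(reldev)))
    B <- B * (kappa / s)
    data[, parts] <- B
  }
  attr(data, "validation_report") <- list(
    n_rows = nrow(data), n_reclosed = length(reclosed),
    max_relative_deviation = max(reldev), kappa = kappa,
    tolerance = tolerance)
  data
}

#' Append olr coordinates to a validated long table
#'
#' @param data validated long data (see [validate_long()]).
#' @param basis an `"olr_basis"` whose labels are behaviour columns of
#'   `data`.
#' @return `data` with D-1 coordinate columns appended (named as the basis
#'   coordinates, `z1..z(D-1)`); behaviour columns are preserved.
#' @export
compute_olr <- function(data, basis) {
  stopifnot(inherits(basis, "olr_basis"))
  missing_cols <- setdiff(basis$labels, names(data))
  if (length(missing_cols) > 0L) {
    stop("basis parts not in data: ", paste(missing_cols, collapse = ", "))
  }
  B <- as.matrix(data[, basis$labels, drop = FALSE])
  if (any(!is.finite(B) | B <= 0)) {
    stop("behaviour columns must be strictly positive and finite; ",
         "run validate_long() first")
  }
  Z <- log(B) %*% basis$contrast
  zn <- colnames(basis$contrast)
  if (any(zn %in% names(data))) {
    stop("data already contains column(s) ", paste(intersect(zn, names(data)),
                                                   collapse = ", "))
  }
  data[, zn] <- Z
  attr(data, "olr_coords") <- zn
  data
}

#' Stack olr coordinates into the single-response layout
#'
#' Restructures a table with D-1 coordinate columns into the long "stacked
#' response" layout used to express the multivariate mixed model as a
#' univariate one: one row per (record, coordinate) with the coordinate value
#' in `olr_value`, the coordinate identity in the factor `response`, and
#' one-hot indicator columns `d1..d(D-1)`. All predictor columns are
#' replicated across the D-1 rows of each source record.
#'
#' @param data output of [compute_olr()], or any data.frame containing the
#'   columns named in `coords`.
#' @param coords names of the coordinate columns; defaults to the
#'   `"olr_coords"` attribute left by [compute_olr()].
#' @return A stacked data.frame with `nrow(data) * (D-1)` rows. The source
#'   row index is kept in `.record` so that [unstack_olr()] is an exact
#'   inverse.
#' @export
stack_olr <- function(data, coords = attr(data, "olr_coords")) {
  if (is.null(coords)) stop("'coords' not given and no \"olr_coords\" attribute")
  missing_cols <- setdiff(coords, names(data))
  if (length(missing_cols) > 0L) {
    stop("coordinate column(s) not in data: ",
         paste(missing_cols, collapse = ", "))
  }
  R <- length(coords)
  n <- nrow(data)
  keep <- setdiff(names(data), coords)
  idx <- rep(seq_len(n), each = R)
  out <- data[idx, keep, drop = FALSE]
  out$.record <- idx
  out$response <- factor(rep(coords, times = n), levels = coords)
  out$olr_value <- as.vector(t(as.matrix(data[, coords, drop = FALSE])))
  for (r in seq_len(R)) {
    out[[paste0("d", r)]] <- as.integer(out$response == coords[r])
  }
  rownames(out) <- NULL
  attr(out, "olr_coords") <- coords
  out
}

#' @rdname stack_olr
#' @param stacked a stacked data.frame produced by [stack_olr()].
#' @export
unstack_olr <- function(stacked) {
  coords <- attr(stacked, "olr_coords")
  if (is.null(coords)) coords <- levels(stacked$response)
  R <- length(coords)
  n <- nrow(stacked) / R
  if (n != round(n)) stop("stacked row count is not a multiple of D-1")
  ord <- order(stacked$.record, as.integer(stacked$response))
  stacked <- stacked[ord, , drop = FALSE]
  first <- stacked[seq(1L, nrow(stacked), by = R), , drop = FALSE]
  drop_cols <- c(".record", "response", "olr_value", paste0("d", seq_len(R)))
  out <- first[, setdiff(names(first), drop_cols), drop = FALSE]
  Z <- matrix(stacked$olr_value, ncol = R, byrow = TRUE)
  colnames(Z) <- coords
  out[, coords] <- Z
  rownames(out) <- NULL
  attr(out, "olr_coords") <- coords
  out
}
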