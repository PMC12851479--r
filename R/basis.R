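#' Orthonormal log-ratio (olr) bases
#'
#' An olr (also called ilr) basis for D-part compositions is represented by a
#' `D x (D-1)` contrast matrix `V` with orthonormal, zero-sum columns:
#' `olr(x) = t(V) %*% log(x)` and `olr_inv(z) = C[exp(V %*% z)]`.
#' Bases are built either from a sequential binary partition (SBP) sign
#' matrix, or as pivot coordinates. Column `j` of an SBP basis carries
#' coefficient `+sqrt(n_j / (p_j (p_j + n_j)))` on the `p_j` numerator
#' (`+1`) parts and `-sqrt(p_j / (n_j (p_j + n_j)))` on the `n_j` denominator
#' (`-1`) parts, so each coordinate is a balance: the scaled log-ratio of the
#' geometric means of two groups of parts.
#'
#' @name olr_basis
NULL

#' Validate a sequential binary partition sign matrix
#'
#' A valid SBP sign matrix is `(D-1) x D` over `{-1, 0, +1}`: its first row
#' splits all D parts into a `+1` and a `-1` group, and every later row
#' splits exactly one previously created group, until all groups are
#' singletons. Each row must have at least one `+1` and one `-1`.
#'
#' @param signs numeric matrix over `{-1, 0, 1}`, one row per balance.
#' @param labels part names, one per column.
#' @return The sign matrix with dimnames set, invisibly usable downstream.
#' @export
validate_sbp <- function(signs, labels = colnames(signs)) {
  signs <- as.matrix(signs)
  D <- ncol(signs)
  if (is.null(labels)) labels <- paste0("x", seq_len(D))
  if (length(labels) != D) stop("'labels' must have one entry per column")
  if (nrow(signs) != D - 1L) {
    stop(sprintf("SBP sign matrix must have D-1 = %d rows, got %d",
                 D - 1L, nrow(signs)))
  }
  if (!all(signs %in% c(-1, 0, 1))) {
    stop("SBP entries must be -1, 0 or +1")
  }
  for (j in seq_len(nrow(signs))) {
    if (!any(signs[j, ] == 1) || !any(signs[j, ] == -1)) {
      stop(sprintf("SBP row %d must contain at least one +1 and one -1", j))
    }
  }
  # each row must split one currently open block; the first block is all parts
  open <- list(seq_len(D))
  for (j in seq_len(nrow(signs))) {
    nz <- which(signs[j, ] != 0)
    hit <- which(vapply(open, function(b) length(b) == length(nz) &&
                          all(sort(b) == sort(nz)), logical(1)))
    if (length(hit) != 1L) {
      stop(sprintf(paste0("SBP row %d does not partition a single block left ",
                          "by earlier rows (parts %s)"),
                   j, paste(labels[nz], collapse = ",")))
    }
    plus <- which(signs[j, ] == 1)
    minus <- which(signs[j, ] == -1)
    open <- open[-hit]
    if (length(plus) > 1L) open <- c(open, list(plus))
    if (length(minus) > 1L) open <- c(open, list(minus))
  }
  if (length(open) > 0L) {
    stop("SBP rows do not reduce all groups to singletons")
  }
  dimnames(signs) <- list(paste0("z", seq_len(D - 1L)), labels)
  signs
}

new_olr_basis <- function(contrast, labels, provenance, sbp = NULL) {
  dimnames(contrast) <- list(labels, paste0("z", seq_len(ncol(contrast))))
  structure(list(contrast = contrast, labels = labels,
                 provenance = provenance, sbp = sbp),
            class = "olr_basis")
}

#' Build an olr basis from an SBP sign matrix
#'
#' @inheritParams validate_sbp
#' @return An object of class `"olr_basis"` with elements `contrast`
#'   (`D x (D-1)` matrix), `labels`, `provenance` and, for SBP bases, the
#'   validated sign matrix `sbp`.
#' @examples
#' # sleep vs waking, SB vs active, LPA vs MVPA
#' sbp <- rbind(c(1, -1, -1, -1), c(0, 1, -1, -1), c(0, 0, 1, -1))
#' sbp_basis(sbp, labels = c("sleep", "sb", "lpa", "mvpa"))
#' @export
sbp_basis <- function(signs, labels = colnames(signs)) {
  signs <- validate_sbp(signs, labels)
  labels <- colnames(signs)
  D <- ncol(signs)
  V <- matrix(0, D, D - 1L)
  for (j in seq_len(D - 1L)) {
    p <- sum(signs[j, ] == 1)
    n <- sum(signs[j, ] == -1)
    V[signs[j, ] == 1, j] <- sqrt(n / (p * (p + n)))
    V[signs[j, ] == -1, j] <- -sqrt(p / (n * (p + n)))
  }
  new_olr_basis(V, labels, "sbp", sbp = signs)
}

#' Pivot-coordinate olr basis
#'
#' Coordinate `j` contrasts part `j` against the geometric mean of parts
#' `j+1, ..., D`; the first coordinate is proportional to the first clr
#' coordinate by the factor `sqrt(D/(D-1))`. Useful when one part (e.g. one
#' behaviour) is of primary interest.
#'
#' @param labels part names in pivot order, or a single integer D (parts are
#'   then named `x1..xD`).
#' @return An `"olr_basis"`.
#' @export
pivot_basis <- function(labels) {
  if (is.numeric(labels) && length(labels) == 1L) {
    labels <- paste0("x", seq_len(labels))
  }
  D <- length(labels)
  if (D < 2L) stop("need at least two parts")
  signs <- matrix(0, D - 1L, D)
  for (j in seq_len(D - 1L)) {
    signs[j, j] <- 1
    signs[j, (j + 1L):D] <- -1
  }
  b <- sbp_basis(signs, labels)
  b$provenance <- "pivot"
  b
}

#' A user-supplied contrast matrix as an olr basis
#'
#' @param contrast `D x (D-1)` matrix with orthonormal zero-sum columns.
#' @param labels part names.
#' @export
custom_basis <- function(contrast, labels = rownames(contrast)) {
  contrast <- as.matrix(contrast)
  if (is.null(labels)) labels <- paste0("x", seq_len(nrow(contrast)))
  b <- new_olr_basis(contrast, labels, "custom")
  chk <- crossprod(contrast)
  if (max(abs(chk - diag(ncol(contrast)))) > 1e-8 ||
      max(abs(colSums(contrast))) > 1e-8) {
    stop("contrast columns must be orthonormal with zero column sums")
  }
  b
}

#' @export
print.olr_basis <- function(x, digits = 4, ...) {
  cat(sprintf("olr basis (%s) for %d parts: %s\n", x$provenance,
              length(x$labels), paste(x$labels, collapse = ", ")))
  print(round(x$contrast, digits))
  invisible(x)
}

#' Read an SBP basis from a YAML or JSON configuration file
#'
#' The file must contain `labels` (character vector) and `sbp` (list of rows
#' over -1/0/1). Validation is applied on load.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return An `"olr_basis"`.
#' @export
read_basis <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyMatrix = FALSE),
    stop("unsupported basis file extension: ", ext)
  )
  if (is.null(cfg$labels) || is.null(cfg$sbp)) {
    stop("basis file must provide 'labels' and 'sbp'")
  }
  signs <- do.call(rbind, lapply(cfg$sbp, as.numeric))
  colnames(signs) <- cfg$labels
  sbp_basis(signs, cfg$labels)
}

#' olr coordinates of a composition
#'
#' @param x a `"composition"` whose part labels match the basis, or a strictly
#'   positive numeric vector in basis part order.
#' @param basis an `"olr_basis"`.
#' @return Numeric vector of length D-1 (names `z1..z(D-1)`).
#' @export
olr <- function(x, basis) {
  stopifnot(inherits(basis, "olr_basis"))
  if (inherits(x, "composition")) {
    if (!identical(names(x), basis$labels)) {
      stop("composition part labels do not match basis labels")
    }
    v <- unclass(x)
  } else {
    v <- as.numeric(x)
    if (length(v) != length(basis$labels)) {
      stop("length of 'x' does not match basis dimension")
    }
    if (any(!is.finite(v) | v <= 0)) stop("parts must be strictly positive")
  }
  drop(crossprod(basis$contrast, log(v)))
}

#' Inverse olr: coordinates back to a composition
#'
#' @param z numeric vector of length D-1.
#' @param basis an `"olr_basis"`.
#' @param kappa closure constant of the result.
#' @return A `"composition"` closed to `kappa`.
#' @examples
#' b <- sbp_basis(rbind(c(1, -1, -1, -1), c(0, 1, -1, -1), c(0, 0, 1, -1)),
#'                labels = c("sleep", "sb", "lpa", "mvpa"))
#' olr_inv(c(0.83, 0.94, 0.93), b, kappa = 1440)
#' @export
olr_inv <- function(z, basis, kappa = 1) {
  stopifnot(inherits(basis, "olr_basis"))
  z <- as.numeric(z)
  if (length(z) != ncol(basis$contrast)) {
    stop("length of 'z' does not match basis dimension")
  }
  if (any(!is.finite(z))) stop("'z' must be finite")
  composition(exp(drop(basis$contrast %*% z)), kappa = kappa,
              labels = basis$labels)
}

#' Re-express olr coordinates in a different basis
#'
#' Both bases must be over the same parts (same labels in the same order).
#' The map is the orthogonal rotation `t(V_to) %*% V_from`.
#'
#' @param z coordinate vector (or matrix with D-1 columns, one row per
#'   observation) in basis `from`.
#' @param from,to `"olr_basis"` objects over the same parts.
#' @return Coordinates in basis `to`, same shape as `z`.
#' @export
change_of_basis <- function(z, from, to) {
  stopifnot(inherits(from, "olr_basis"), inherits(to, "olr_basis"))
  if (!identical(from$labels, to$labels)) {
    stop("bases are over different parts")
  }
  R <- crossprod(to$contrast, from$contrast)
  if (is.matrix(z)) z %*% t(R) else drop(R %*% as.numeric(z))
}
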