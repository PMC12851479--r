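# Estimation engine for the multivariate-response mixed model.
#
# Per subject i with J_i observed occasions and R = D-1 response coordinates,
# the stacked response y_i (occasion-major, coordinates inner) is
#   y_i ~ MVN(X_i beta, V_i),   V_i = 1_{J_i} 1'_{J_i} (x) G + I_{J_i} (x) E
# so V_i depends on the subject only through J_i. Subjects are grouped by
# J_i; per group one Cholesky of the (J R) x (J R) block is taken and all
# subjects of the group are whitened in a single triangular solve. beta is
# profiled out by GLS, leaving the covariance parameters (log-Cholesky of G
# and E) to a quasi-Newton optimiser.

# log-Cholesky parameterisation ------------------------------------------

theta_length <- function(R, structure) {
  if (structure == "unstructured") R * (R + 1L) / 2L else R
}

theta_to_cov <- function(theta, R, structure) {
  if (structure == "diagonal") {
    return(diag(exp(2 * theta), R, R))
  }
  U <- matrix(0, R, R)
  diag(U) <- exp(theta[seq_len(R)])
  if (R > 1L) U[upper.tri(U)] <- theta[-seq_len(R)]
  crossprod(U)
}

cov_to_theta <- function(M, structure) {
  R <- nrow(M)
  if (structure == "diagonal") {
    return(0.5 * log(pmax(diag(M), 1e-10)))
  }
  U <- chol(M)
  c(log(diag(U)), U[upper.tri(U)])
}

# build the compound block covariance for J occasions
block_cov <- function(J, G, E) {
  kronecker(matrix(1, J, J), G) + kronecker(diag(J), E)
}

# data preparation --------------------------------------------------------

# Z: n_long x R response matrix; X0: n_long x q base design; subject: factor.
# Rows are reordered so each subject's records are contiguous; `order` maps
# engine (sorted) long rows back to input rows via input = engine$order.
prepare_engine <- function(Z, X0, subject) {
  Z <- as.matrix(Z)
  X0 <- as.matrix(X0)
  subject <- factor(subject)
  ord <- order(as.integer(subject))
  Z <- Z[ord, , drop = FALSE]
  X0 <- X0[ord, , drop = FALSE]
  subject <- subject[ord]
  n_long <- nrow(Z)
  R <- ncol(Z)
  q <- ncol(X0)
  J <- as.integer(table(subject))
  names(J) <- levels(subject)

  # stacked response and design: long-row-major, coordinates inner
  y <- as.vector(t(Z))
  X <- matrix(0, n_long * R, q * R)
  for (r in seq_len(R)) {
    X[seq(r, n_long * R, by = R), (r - 1L) * q + seq_len(q)] <- X0
  }
  zn <- colnames(Z)
  if (is.null(zn)) zn <- paste0("z", seq_len(R))
  colnames(X) <- paste(rep(zn, each = q), rep(colnames(X0), R), sep = ":")

  # stacked row ranges per subject (subjects contiguous after sorting)
  ends_long <- cumsum(J)
  starts_long <- c(1L, utils::head(ends_long, -1L) + 1L)
  # group subjects by J
  groups <- split(seq_along(J), J)
  patterns <- lapply(groups, function(subj_idx) {
    Jg <- J[subj_idx[1L]]
    rows <- unlist(lapply(subj_idx, function(s) {
      ((starts_long[s] - 1L) * R + 1L):(ends_long[s] * R)
    }), use.names = FALSE)
    list(J = Jg, subjects = subj_idx, rows = rows, m = length(subj_idx))
  })
  list(Z = Z, X0 = X0, subject = subject, order = ord, y = y, X = X,
       n_long = n_long, R = R, q = q, p = q * R, J = J,
       starts_long = starts_long, ends_long = ends_long,
       patterns = patterns, coord_names = zn,
       n_obs = n_long * R, n_subjects = length(J))
}

# criterion ---------------------------------------------------------------

# Returns -2 * (restricted) log-likelihood at (G, E) with beta profiled out,
# plus the profiled beta and the GLS information matrix.
profiled_neg2ll <- function(engine, G, E, method = "REML") {
  R <- engine$R
  p <- engine$p
  n <- engine$n_obs
  A <- matrix(0, p + 1L, p + 1L) # crossprod of whitened [X, y]
  sumlogdet <- 0
  for (pat in engine$patterns) {
    b <- pat$J * R
    V <- block_cov(pat$J, G, E)
    U <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(U)) return(list(neg2ll = 1e10, ok = FALSE))
    sumlogdet <- sumlogdet + pat$m * 2 * sum(log(diag(U)))
    Wy <- cbind(engine$X[pat$rows, , drop = FALSE], engine$y[pat$rows])
    # whiten all m subjects of the pattern in one triangular solve:
    # reshape (m*b) x (p+1) -> b x (m*(p+1)), solve t(U) x = ., reshape back
    mat <- matrix(array(Wy, c(b, pat$m, p + 1L)), b, pat$m * (p + 1L))
    wt <- backsolve(U, mat, transpose = TRUE)
    Wt <- matrix(wt, pat$m * b, p + 1L)
    A <- A + crossprod(Wt)
  }
  XtX <- A[seq_len(p), seq_len(p), drop = FALSE]
  Xty <- A[seq_len(p), p + 1L]
  yty <- A[p + 1L, p + 1L]
  cX <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(cX)) return(list(neg2ll = 1e10, ok = FALSE))
  beta <- backsolve(cX, backsolve(cX, Xty, transpose = TRUE))
  rss <- yty - sum(Xty * beta)
  neg2ll <- if (method == "REML") {
    (n - p) * log(2 * pi) + sumlogdet + 2 * sum(log(diag(cX))) + rss
  } else {
    n * log(2 * pi) + sumlogdet + rss
  }
  list(neg2ll = neg2ll, beta = beta, XtX = XtX, cholXtX = cX, ok = TRUE)
}

# starting values ---------------------------------------------------------

start_covariances <- function(engine) {
  R <- engine$R
  fit0 <- stats::lm.fit(engine$X0, engine$Z)
  res <- as.matrix(fit0$residuals)
  sub <- engine$subject
  M <- apply(res, 2L, function(col) tapply(col, sub, mean))
  M <- matrix(M, ncol = R)
  within <- res - M[as.integer(sub), , drop = FALSE]
  nw <- max(engine$n_long - engine$n_subjects, R + 1L)
  E0 <- crossprod(within) / nw
  Jbar <- mean(1 / engine$J)
  G0 <- stats::cov(M) - Jbar * E0
  # ensure positive definiteness of the starts
  fix_pd <- function(M) {
    M <- (M + t(M)) / 2
    ev <- eigen(M, symmetric = TRUE)
    lam <- pmax(ev$values, 1e-4 * max(abs(ev$values), 1e-4))
    ev$vectors %*% (lam * t(ev$vectors))
  }
  list(G = fix_pd(G0), E = fix_pd(E0))
}

# optimiser ---------------------------------------------------------------

#' Control parameters for [cmrlmm()]
#'
#' @param maxit maximum BFGS iterations per start.
#' @param reltol relative convergence tolerance on the criterion.
#' @param grad_tol declare convergence when the infinity norm of the
#'   numerical gradient is below `grad_tol * (1 + |criterion|)`.
#' @param restarts maximum number of additional starts with perturbed
#'   covariance parameters when the first run fails the gradient check.
#' @param boundary_tol relative eigenvalue threshold below which a fitted
#'   covariance matrix is reported as near-singular (boundary fit).
#' @param polish apply a Newton polish (numerical Hessian) after the BFGS
#'   run, sharpening the optimum so that rotation-equivalent fits agree to
#'   high precision; skipped automatically at boundary fits.
#' @return A list of class `"cmrlmm_control"`.
#' @export
cmrlmm_control <- function(maxit = 500L, reltol = 1e-10, grad_tol = 1e-6,
                           restarts = 3L, boundary_tol = 1e-7,
                           polish = TRUE) {
  structure(list(maxit = maxit, reltol = reltol, grad_tol = grad_tol,
                 restarts = restarts, boundary_tol = boundary_tol,
                 polish = polish),
            class = "cmrlmm_control")
}

num_gradient <- function(fn, x, h = 1e-6) {
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    hk <- h * (1 + abs(x[k]))
    xp <- x; xp[k] <- x[k] + hk
    xm <- x; xm[k] <- x[k] - hk
    g[k] <- (fn(xp) - fn(xm)) / (2 * hk)
  }
  g
}

# A few damped Newton steps with a finite-difference Hessian; sharpens the
# BFGS optimum (gradient inf-norm to ~1e-6) so that fits of the same model
# in rotated coordinate systems agree to high precision after
# back-transformation.
newton_polish <- function(objective, theta, grad_h = 1e-5, max_steps = 3L) {
  p <- length(theta)
  g <- num_gradient(objective, theta, h = grad_h)
  f <- objective(theta)
  H <- matrix(0, p, p)
  for (k in seq_len(p)) {
    hk <- 1e-4 * (1 + abs(theta[k]))
    tp <- theta; tp[k] <- theta[k] + hk
    H[, k] <- (num_gradient(objective, tp, h = grad_h) - g) / hk
  }
  H <- (H + t(H)) / 2
  for (it in seq_len(max_steps)) {
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- theta - step
    fc <- objective(cand)
    if (!is.finite(fc) || fc > f + 1e-10) break
    theta <- cand; f <- fc
    g <- num_gradient(objective, theta, h = grad_h)
    if (max(abs(g)) < 1e-8 * (1 + abs(f))) break
  }
  list(theta = theta, value = f, gnorm = max(abs(g)))
}

fit_engine <- function(engine, g_structure, e_structure, method,
                       control = cmrlmm_control()) {
  R <- engine$R
  nG <- theta_length(R, g_structure)
  nE <- theta_length(R, e_structure)
  starts <- start_covariances(engine)
  theta0 <- c(cov_to_theta(starts$G, g_structure),
              cov_to_theta(starts$E, e_structure))
  objective <- function(theta) {
    G <- theta_to_cov(theta[seq_len(nG)], R, g_structure)
    E <- theta_to_cov(theta[nG + seq_len(nE)], R, e_structure)
    0.5 * profiled_neg2ll(engine, G, E, method)$neg2ll
  }
  eig_ratio <- function(theta) {
    G <- theta_to_cov(theta[seq_len(nG)], R, g_structure)
    E <- theta_to_cov(theta[nG + seq_len(nE)], R, e_structure)
    vapply(list(G = G, E = E), function(M) {
      ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
      min(ev) / max(ev)
    }, numeric(1))
  }
  best <- NULL
  n_restarts_used <- 0L
  for (attempt in 0:control$restarts) {
    th <- if (attempt == 0L) theta0 else {
      # deterministic jitter so refits are reproducible
      theta0 + 0.15 * attempt * cos(seq_along(theta0) * (attempt + 1))
    }
    opt <- stats::optim(th, objective,
                        gr = function(x) num_gradient(objective, x),
                        method = "BFGS",
                        control = list(maxit = control$maxit,
                                       reltol = control$reltol))
    g <- num_gradient(objective, opt$par)
    gnorm <- max(abs(g))
    boundary <- any(eig_ratio(opt$par) < control$boundary_tol)
    # at a boundary (a variance or eigenvalue heading to zero) the interior
    # first-order condition is unattainable; accept the optimiser's
    # relative-change criterion there, under a looser gradient cap
    ok <- opt$convergence == 0L &&
      (gnorm <= control$grad_tol * (1 + abs(opt$value)) ||
         (boundary && gnorm <= 1e3 * control$grad_tol * (1 + abs(opt$value))))
    if (is.null(best) || opt$value < best$opt$value - 1e-9) {
      best <- list(opt = opt, gnorm = gnorm, ok = ok, boundary = boundary)
    } else if (ok && !best$ok && opt$value < best$opt$value + 1e-6) {
      best <- list(opt = opt, gnorm = gnorm, ok = ok, boundary = boundary)
    }
    n_restarts_used <- attempt
    if (best$ok) break
  }
  opt <- best$opt
  theta <- opt$par
  if (isTRUE(control$polish) && !best$boundary) {
    pol <- newton_polish(objective, theta, grad_h = 1e-5)
    if (pol$value <= opt$value + 1e-10) {
      theta <- pol$theta
      best$gnorm <- pol$gnorm
      opt$value <- pol$value
      best$ok <- opt$convergence == 0L &&
        best$gnorm <= control$grad_tol * (1 + abs(opt$value))
    }
  }
  G <- theta_to_cov(theta[seq_len(nG)], R, g_structure)
  E <- theta_to_cov(theta[nG + seq_len(nE)], R, e_structure)
  final <- profiled_neg2ll(engine, G, E, method)
  if (!best$ok) {
    warning(sprintf(paste0("optimiser did not meet the convergence criteria ",
                           "(gradient inf-norm %.2e after %d restart(s))"),
                    best$gnorm, n_restarts_used))
  }
  for (nm in c("G", "E")) {
    M <- if (nm == "G") G else E
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < control$boundary_tol * max(ev)) {
      warning(sprintf("boundary fit: %s matrix is near-singular (min/max eigenvalue ratio %.2e)",
                      nm, min(ev) / max(ev)))
    }
  }
  dimnames(G) <- dimnames(E) <- list(engine$coord_names, engine$coord_names)
  vcov_beta <- chol2inv(final$cholXtX)
  beta <- drop(final$beta)
  names(beta) <- colnames(engine$X)
  dimnames(vcov_beta) <- list(names(beta), names(beta))
  blups <- compute_blups(engine, beta, G, E)
  list(beta = beta, vcov_beta = vcov_beta, G = G, E = E,
       loglik = -0.5 * final$neg2ll, theta = theta, blups = blups,
       converged = best$ok, boundary = best$boundary,
       optim = list(value = opt$value,
                                         counts = opt$counts,
                                         convergence = opt$convergence,
                                         gradient_norm = best$gnorm,
                                         restarts = n_restarts_used),
       n_cov_params = nG + nE)
}

# BLUPs of the subject random-intercept vectors: b_i = G Z_i' V_i^{-1} r_i,
# with Z_i' V_i^{-1} r_i the occasion-sum of the R-blocks of V_i^{-1} r_i.
compute_blups <- function(engine, beta, G, E) {
  R <- engine$R
  r <- engine$y - drop(engine$X %*% beta)
  B <- matrix(0, engine$n_subjects, R,
              dimnames = list(levels(engine$subject), engine$coord_names))
  for (pat in engine$patterns) {
    b <- pat$J * R
    V <- block_cov(pat$J, G, E)
    U <- chol(V)
    mat <- matrix(r[pat$rows], b, pat$m)
    u <- backsolve(U, backsolve(U, mat, transpose = TRUE)) # V^-1 r per subject
    # sum the J occasion blocks of length R
    t_i <- matrix(0, R, pat$m)
    for (j in seq_len(pat$J)) {
      t_i <- t_i + u[(j - 1L) * R + seq_len(R), , drop = FALSE]
    }
    B[pat$subjects, ] <- t(G %*% t_i)
  }
  B
}

#' Evaluate the model log-likelihood at explicit parameter values
#'
#' Assembles each subject's dense marginal covariance
#' `V_i = Z_i G Z_i' + I (x) E` and evaluates the multivariate-normal
#' log-density (restricted log-likelihood under `method = "REML"`) directly
#' with generic determinants and solves. This is deliberately a separate,
#' naive code path from the optimised fitting routine, so it can serve as an
#' oracle for the fitted criterion: at the fitted parameters it must
#' reproduce `logLik(fit)`.
#'
#' @param fit a fitted [cmrlmm()] (or comparator) model object.
#' @param beta fixed-effect vector in the order of `coef(fit)`; defaults to
#'   the fitted coefficients.
#' @param G,E covariance matrices of the random intercepts and residuals;
#'   default to the fitted matrices.
#' @param method `"REML"` or `"ML"`; defaults to the fit's method.
#' @return The log-likelihood (a single number).
#' @export
loglik_oracle <- function(fit, beta = fit$beta, G = fit$G, E = fit$E,
                          method = fit$method) {
  engine <- fit$engine
  if (is.null(engine)) stop("fit does not carry its engine data")
  G <- as.matrix(G); E <- as.matrix(E)
  ev <- function(M) eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev(G)) <= 0 && max(abs(G)) > 0) stop("G is not positive definite")
  if (min(ev(E)) <= 0) stop("E is not positive definite")
  R <- engine$R
  ll <- 0
  XtVX <- matrix(0, engine$p, engine$p)
  for (s in seq_len(engine$n_subjects)) {
    rows <- ((engine$starts_long[s] - 1L) * R + 1L):(engine$ends_long[s] * R)
    Js <- engine$J[s]
    Zi <- kronecker(matrix(1, Js, 1L), diag(R))
    Vi <- Zi %*% G %*% t(Zi) + kronecker(diag(Js), E)
    ri <- engine$y[rows] - drop(engine$X[rows, , drop = FALSE] %*% beta)
    Vinv <- solve(Vi)
    ld <- as.numeric(determinant(Vi, logarithm = TRUE)$modulus)
    ll <- ll - 0.5 * (length(ri) * log(2 * pi) + ld +
                        drop(crossprod(ri, Vinv %*% ri)))
    XtVX <- XtVX + crossprod(engine$X[rows, , drop = FALSE],
                             Vinv %*% engine$X[rows, , drop = FALSE])
  }
  if (method == "REML") {
    ll <- ll + 0.5 * engine$p * log(2 * pi) -
      0.5 * as.numeric(determinant(XtVX, logarithm = TRUE)$modulus)
  }
  ll
}

#' Generalised least squares coefficients at explicit covariance values
#'
#' Direct GLS solve `beta = (sum X_i' V_i^{-1} X_i)^{-1} sum X_i' V_i^{-1} y_i`
#' with dense per-subject covariances; an independent check of the profiled
#' coefficients returned by the optimiser.
#'
#' @inheritParams loglik_oracle
#' @return Named coefficient vector.
#' @export
gls_oracle <- function(fit, G = fit$G, E = fit$E) {
  engine <- fit$engine
  R <- engine$R
  XtVX <- matrix(0, engine$p, engine$p)
  XtVy <- numeric(engine$p)
  for (s in seq_len(engine$n_subjects)) {
    rows <- ((engine$starts_long[s] - 1L) * R + 1L):(engine$ends_long[s] * R)
    Js <- engine$J[s]
    Vi <- kronecker(matrix(1, Js, Js), as.matrix(G)) +
      kronecker(diag(Js), as.matrix(E))
    Vinv <- solve(Vi)
    Xi <- engine$X[rows, , drop = FALSE]
    XtVX <- XtVX + crossprod(Xi, Vinv %*% Xi)
    XtVy <- XtVy + drop(crossprod(Xi, Vinv %*% engine$y[rows]))
  }
  beta <- drop(solve(XtVX, XtVy))
  names(beta) <- colnames(engine$X)
  beta
}
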