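# End-to-end pipeline: a single configuration drives validate -> olr ->
# stack -> fit (full + comparators) -> tests -> back-transform -> optional
# bootstrap, with all tables written as CSV and a machine-readable JSON
# summary. The functions and the config file are the package's scripted
# interface; every default used is echoed into the output so runs are
# self-describing.

#' Assemble and validate a pipeline configuration
#'
#' @param config a named list, or the path of a YAML/JSON file containing
#'   one. Recognised fields: `input` (CSV path) or `data` (data.frame);
#'   `parts` (ordered behaviour columns); `subject`; `occasion`; `kappa`;
#'   `formula` (right-hand side, e.g. `"~ occasion + zbmi + income"`);
#'   `basis` (`"pivot"` or a list with `sbp` rows and `labels`);
#'   `g_structure`; `e_structure`; `method`; `bootstrap` (list with `B`,
#'   `level`, `seed`, `quantity = "predictions"`); `output_dir`; `seed`.
#' @return A validated config list with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      yaml = , yml = yaml::read_yaml(config),
      json = jsonlite::fromJSON(config, simplifyMatrix = FALSE),
      stop("unsupported config extension: ", ext))
  }
  if (!is.list(config)) stop("'config' must be a list or a YAML/JSON path")
  defaults <- list(occasion = NULL, kappa = NULL, formula = "~ occasion",
                   basis = "pivot", g_structure = "unstructured",
                   e_structure = "unstructured", method = "REML",
                   tolerance = 0.05, bootstrap = NULL,
                   output_dir = NULL, seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("parts", "subject")) {
    if (is.null(config[[nm]])) stop("config field missing: $", nm)
  }
  if (is.null(config$data)) {
    if (is.null(config$input)) stop("config needs $input (CSV path) or $data")
    config$data <- utils::read.csv(config$input, stringsAsFactors = FALSE)
  }
  config$data[[config$subject]] <- as.character(config$data[[config$subject]])
  if (identical(config$basis, "pivot")) {
    config$basis_obj <- pivot_basis(config$parts)
  } else if (is.list(config$basis)) {
    signs <- do.call(rbind, lapply(config$basis$sbp, as.numeric))
    labels <- if (is.null(config$basis$labels)) config$parts else
      config$basis$labels
    config$basis_obj <- sbp_basis(signs, labels)
  } else if (inherits(config$basis, "olr_basis")) {
    config$basis_obj <- config$basis
  } else {
    stop("config $basis must be \"pivot\", an sbp list, or an olr_basis")
  }
  if (!identical(sort(config$basis_obj$labels), sort(config$parts))) {
    stop("config $basis labels must match $parts")
  }
  config
}

pipeline_formula <- function(config) {
  lhs <- paste0("cbind(", paste(config$parts, collapse = ", "), ")")
  rhs <- sub("^~\\s*", "", config$formula)
  stats::as.formula(paste(lhs, "~", rhs))
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Run the full analysis pipeline from a configuration
#'
#' Validates the data, fits the full joint model and the diagonal
#' (unrelated-outcomes) comparator, runs joint F tests and the
#' likelihood-ratio test between the two covariance structures,
#' back-transforms coefficients and reference-grid predictions to
#' compositions, optionally bootstraps the predictions, and writes all
#' tables to `output_dir` (coefficients, compositional coefficients, joint
#' tests, LRT, predictions, plus `summary.json`).
#'
#' @param config see [run_config()].
#' @param verbose log per-stage progress.
#' @return Invisibly, a list with the fitted models, the tables and the
#'   paths of the written files.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  config <- run_config(config)
  formula <- pipeline_formula(config)
  stage_log(verbose, "validate + olr + stack: %d rows", nrow(config$data))
  fit <- cmrlmm(formula, config$data, subject = config$subject,
                occasion = config$occasion, basis = config$basis_obj,
                kappa = config$kappa, g_structure = config$g_structure,
                e_structure = config$e_structure, method = config$method,
                tolerance = config$tolerance)
  report <- attr(fit$data, "validation_report")
  if (!is.null(report) && report$n_reclosed > 0) {
    stage_log(verbose, "cleaning: %d row(s) re-closed to kappa = %g",
              report$n_reclosed, report$kappa)
  }
  stage_log(verbose, "full fit done (logLik %.2f, %d params)",
            fit$loglik, fit$n_params)
  fit_diag <- cmrlmm(formula, config$data, subject = config$subject,
                     occasion = config$occasion, basis = config$basis_obj,
                     kappa = config$kappa, g_structure = "diagonal",
                     e_structure = "diagonal", method = config$method,
                     tolerance = config$tolerance)
  stage_log(verbose, "unrelated (diagonal) fit done (logLik %.2f, %d params)",
            fit_diag$loglik, fit_diag$n_params)

  tests <- joint_tests(fit)
  lrt_tab <- anova(fit, fit_diag)
  ctab <- coef_tests(fit)
  ctab <- cbind(coefficient = rownames(ctab), ctab)
  rownames(ctab) <- NULL
  ccoef <- compositional_coef(fit)
  grid <- try(reference_grid(fit), silent = TRUE)
  preds <- NULL
  if (!inherits(grid, "try-error")) {
    pc <- predict(fit, newdata = grid$data, type = "composition")
    preds <- data.frame(setting = grid$levels, pc, check.names = FALSE)
  }
  boot <- NULL
  if (!is.null(config$bootstrap) && !is.null(preds)) {
    bs <- config$bootstrap
    B <- if (is.null(bs$B)) 1000L else bs$B
    lev <- if (is.null(bs$level)) 0.95 else bs$level
    bseed <- if (is.null(bs$seed)) config$seed else bs$seed
    gd <- grid$data
    qfun <- function(f) as.vector(t(predict(f, newdata = gd,
                                            type = "composition")))
    stage_log(verbose, "cases bootstrap: B = %d", B)
    boot <- cases_bootstrap(fit, qfun, B = B, seed = bseed, level = lev)
    k <- length(fit$parts)
    preds$setting <- as.character(preds$setting)
    for (j in seq_len(k)) {
      preds[[paste0(fit$parts[j], "_lower")]] <-
        boot$lower[seq(j, length(boot$lower), by = k)]
      preds[[paste0(fit$parts[j], "_upper")]] <-
        boot$upper[seq(j, length(boot$upper), by = k)]
    }
  }

  files <- character(0)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(obj, name) {
      path <- file.path(config$output_dir, name)
      utils::write.csv(as.data.frame(obj), path, row.names = FALSE)
      path
    }
    files <- c(coefficients = wr(ctab, "coefficients.csv"),
               compositional_coefficients =
                 wr(ccoef, "compositional_coefficients.csv"),
               joint_tests = wr(tests, "joint_tests.csv"),
               lrt = wr(lrt_tab, "lrt.csv"))
    if (!is.null(preds)) files <- c(files, predictions = wr(preds, "predictions.csv"))
    summary_path <- file.path(config$output_dir, "summary.json")
    summary <- list(
      config = list(parts = config$parts, subject = config$subject,
                    occasion = config$occasion, formula = config$formula,
                    kappa = fit$kappa, basis = config$basis_obj$provenance,
                    sbp = if (!is.null(config$basis_obj$sbp))
                      unname(apply(config$basis_obj$sbp, 1L, as.numeric,
                                   simplify = FALSE)),
                    g_structure = config$g_structure,
                    e_structure = config$e_structure, method = config$method,
                    seed = config$seed),
      cleaning = report,
      fit = list(loglik = fit$loglik, n_params = fit$n_params,
                 AIC = stats::AIC(fit), BIC = stats::BIC(fit),
                 converged = fit$converged,
                 beta = as.list(fit$beta), G = unname(as.data.frame(fit$G)),
                 E = unname(as.data.frame(fit$E))),
      unrelated = list(loglik = fit_diag$loglik,
                       n_params = fit_diag$n_params,
                       AIC = stats::AIC(fit_diag),
                       BIC = stats::BIC(fit_diag)),
      lrt = as.list(lrt_tab[1L, c("L_ratio", "df", "p_value")]),
      joint_tests = tests,
      compositional_coefficients = as.data.frame(ccoef),
      predictions = preds,
      bootstrap = if (!is.null(boot))
        list(B = boot$B, level = boot$level, seed = boot$seed,
             n_failed = boot$n_failed, unreliable = boot$unreliable))
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    files <- c(files, summary = summary_path)
    stage_log(verbose, "wrote %d file(s) to %s", length(files),
              config$output_dir)
  }
  invisible(list(fit = fit, fit_unrelated = fit_diag, coef_tests = ctab,
                 joint_tests = tests, lrt = lrt_tab,
                 compositional_coefficients = ccoef, predictions = preds,
                 bootstrap = boot, files = files, config = config))
}

#' Compare the joint model with the common alternative approaches
#'
#' Fits, on the same data: the full joint model under two different olr
#' bases, the diagonal (unrelated-outcomes) model, per-coordinate univariate
#' suites under both bases, and the per-behaviour raw-minutes suite. Reports
#' the likelihood-ratio test for the covariance structure, the basis
#' discrepancy of fitted compositions for the joint model (which should be
#' numerically zero) and for the univariate suites (which is not), and the
#' largest constant-sum violation of the raw-minutes fits.
#'
#' @param config see [run_config()].
#' @param basis2 second `"olr_basis"` over the same parts; defaults to a
#'   pivot basis with the parts rotated by one position.
#' @param verbose log progress.
#' @return A list with the fits and a `report` list of the comparison
#'   measures.
#' @export
compare_approaches <- function(config, basis2 = NULL, verbose = TRUE) {
  config <- run_config(config)
  formula <- pipeline_formula(config)
  b1 <- config$basis_obj
  if (is.null(basis2)) {
    rotated <- c(b1$labels[-1L], b1$labels[1L])
    basis2 <- pivot_basis(rotated)
  }
  args <- list(formula, config$data, subject = config$subject,
               occasion = config$occasion, kappa = config$kappa,
               method = config$method, tolerance = config$tolerance)
  fit1 <- do.call(cmrlmm, c(args, list(basis = b1)))
  fit2 <- do.call(cmrlmm, c(args, list(basis = basis2)))
  fit_diag <- do.call(cmrlmm, c(args, list(basis = b1,
                                           g_structure = "diagonal",
                                           e_structure = "diagonal")))
  uni1 <- do.call(univariate_suite, c(args, list(basis = b1)))
  uni2 <- do.call(univariate_suite, c(args, list(basis = basis2)))
  raw <- do.call(raw_minutes_suite, c(args, list(parts = config$parts)))

  # align parts: predictions are reported in part order of basis 1
  full1 <- predict(fit1, type = "composition", include_blups = TRUE)
  full2 <- predict(fit2, type = "composition",
                   include_blups = TRUE)[, fit1$parts, drop = FALSE]
  u1 <- suite_fitted_composition(uni1)[, fit1$parts, drop = FALSE]
  u2 <- suite_fitted_composition(uni2)[, fit1$parts, drop = FALSE]
  report <- list(
    full_basis_discrepancy = max(abs(full1 - full2)),
    univariate_basis_discrepancy = max(abs(u1 - u2)),
    lrt = lrt(fit1, fit_diag),
    raw_constant_sum_violation = constant_sum_violation(raw),
    kappa = fit1$kappa)
  stage_log(verbose,
            "basis discrepancy: full %.2e vs univariate %.2e; raw sum violation %.3g",
            report$full_basis_discrepancy,
            report$univariate_basis_discrepancy,
            report$raw_constant_sum_violation)
  invisible(list(fit_basis1 = fit1, fit_basis2 = fit2,
                 fit_unrelated = fit_diag, univariate_basis1 = uni1,
                 univariate_basis2 = uni2, raw = raw, report = report))
}
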