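# shared fixtures built in code

time_use_basis <- loh_basis()   # sleep vs waking, SB vs active, LPA vs MVPA
time_use_alt <- alt_basis()     # a different SBP over the same parts

time_use_formula <- cbind(sleep, sb, lpa, mvpa) ~ occasion + zbmi + income
time_only_formula <- cbind(sleep, sb, lpa, mvpa) ~ occasion

# a random strictly-positive 4-part composition
rand_comp <- function(kappa = 1, labels = time_use_basis$labels) {
  composition(exp(stats::rnorm(length(labels), sd = 0.7)), kappa = kappa,
              labels = labels)
}

# moderate-size realistic dataset shared by several model-level tests
medium_data <- make_fixture("loh_like", seed = 4242, n_subjects = 60)

fit_medium <- cmrlmm(time_use_formula, medium_data, subject = "id",
                     basis = time_use_basis, kappa = 1440)

fit_medium_diag <- cmrlmm(time_use_formula, medium_data, subject = "id",
                          basis = time_use_basis, kappa = 1440,
                          g_structure = "diagonal",
                          e_structure = "diagonal")
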