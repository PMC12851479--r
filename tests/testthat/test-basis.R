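test_that("balance coefficients follow the p/n normalisation", {
  b <- time_use_basis
  # first balance: 1 part vs 3
  expect_equal(unname(b$contrast[, 1]),
               c(sqrt(3 / 4), rep(-sqrt(1 / 12), 3)), tolerance = 1e-12)
  # last balance: 1 vs 1
  expect_equal(unname(b$contrast[, 3]),
               c(0, 0, sqrt(1 / 2), -sqrt(1 / 2)), tolerance = 1e-12)
})

test_that("every generated contrast matrix is orthonormal with zero sums", {
  five_part <- sbp_basis(rbind(c(1, 1, -1, -1, -1),
                               c(1, -1, 0, 0, 0),
                               c(0, 0, 1, -1, -1),
                               c(0, 0, 0, 1, -1)),
                         labels = paste0("p", 1:5))
  for (b in list(time_use_basis, time_use_alt, pivot_basis(4),
                 pivot_basis(letters[1:6]), five_part)) {
    D <- length(b$labels)
    expect_equal(crossprod(b$contrast), diag(D - 1), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_lt(max(abs(colSums(b$contrast))), 1e-10)
  }
})

test_that("invalid sign matrices are rejected with the offending row", {
  # row 2 does not split a block left by row 1
  expect_error(sbp_basis(rbind(c(1, -1, -1, -1),
                               c(1, 1, -1, -1),
                               c(0, 0, 1, -1))), "row 2")
  # a row without a denominator group
  expect_error(sbp_basis(rbind(c(1, 1, 1, 1),
                               c(0, 1, -1, -1),
                               c(0, 0, 1, -1))), "row 1")
  # wrong number of rows
  expect_error(sbp_basis(rbind(c(1, -1, -1, -1))), "rows")
  # entries outside -1/0/1
  expect_error(sbp_basis(rbind(c(2, -1, -1, 0),
                               c(0, 1, -1, 0),
                               c(1, 0, 0, -1))), "-1, 0 or \\+1")
})

test_that("the first pivot coordinate is a scaled clr coordinate", {
  set.seed(4)
  b <- pivot_basis(time_use_basis$labels)
  for (i in 1:10) {
    x <- rand_comp()
    expect_equal(olr(x, b)[1], sqrt(4 / 3) * clr(x)[1],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("olr and its inverse are mutually inverse and scale invariant", {
  set.seed(5)
  b1 <- time_use_basis
  b2 <- time_use_alt
  worst <- 0
  for (i in 1:1000) {
    u <- exp(rnorm(4, sd = 1))
    x <- composition(u, kappa = 1440, labels = b1$labels)
    z <- olr(x, b1)
    xx <- olr_inv(z, b1, kappa = 1440)
    worst <- max(worst, max(abs(parts(xx) - parts(x)) / parts(x)))
    # scale invariance: closure constant does not affect coordinates
    expect_equal(olr(clo(u, 1, b1$labels), b1),
                 olr(clo(u, 777, b1$labels), b1), tolerance = 1e-10)
  }
  expect_lt(worst, 1e-9)
  # basis invariance of the round trip
  x <- rand_comp(kappa = 1440)
  expect_equal(olr_inv(olr(x, b1), b1, 1440), olr_inv(olr(x, b2), b2, 1440))
})

test_that("change of basis is the expected orthogonal rotation", {
  b1 <- time_use_basis
  b2 <- time_use_alt
  R <- crossprod(b2$contrast, b1$contrast)
  expect_equal(R %*% t(R), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  set.seed(6)
  z <- rnorm(3)
  z2 <- change_of_basis(z, b1, b2)
  expect_equal(olr_inv(z2, b2), olr_inv(z, b1))
  expect_equal(change_of_basis(z2, b2, b1), z, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(change_of_basis(z, b1, b1), z, ignore_attr = TRUE)
  expect_error(change_of_basis(z, b1, pivot_basis(letters[1:4])),
               "different parts")
})

test_that("bases load from YAML and JSON configuration", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("labels: [sleep, sb, lpa, mvpa]",
               "sbp:",
               "  - [1, -1, -1, -1]",
               "  - [0, 1, -1, -1]",
               "  - [0, 0, 1, -1]"), yml)
  b <- read_basis(yml)
  expect_equal(b$contrast, time_use_basis$contrast)
  jsn <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(labels = c("sleep", "sb", "lpa", "mvpa"),
                                   sbp = list(c(1, -1, -1, -1),
                                              c(0, 1, -1, -1),
                                              c(0, 0, 1, -1)))), jsn)
  expect_equal(read_basis(jsn)$contrast, time_use_basis$contrast)
})

test_that("back-transforming printed coordinate estimates reproduces the worked example", {
  b <- time_use_basis
  baseline <- olr_inv(c(0.83, 0.94, 0.93), b, kappa = 1440)
  expect_equal(round(unname(parts(baseline)[c("sleep", "mvpa")])), c(584, 79))
  t3 <- parts(olr_inv(c(0.09, 0.22, 0.21), b, kappa = 1))
  expect_lt(max(abs(unname(t3) - c(0.266, 0.289, 0.256, 0.190))), 2e-3)
  expect_equal(round(unname(t3["mvpa"]), 3), 0.190)
  t2 <- parts(olr_inv(c(0.01, 0.01, -0.01), b, kappa = 1))
  expect_equal(round(unname(t2["sleep"]), 3), 0.252)
  # the neutral coordinates give the neutral element
  expect_equal(olr_inv(c(0, 0, 0), b, 1440), cneutral(4, 1440, b$labels))
})
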