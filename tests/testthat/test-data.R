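make_long <- function() {
  data.frame(id = rep(c("a", "b"), each = 2),
             occasion = rep(c("T1", "T2"), 2),
             sleep = c(600, 590, 580, 610),
             sb = c(460, 470, 480, 450),
             lpa = c(300, 300, 310, 300),
             mvpa = c(80, 80, 70, 80))
}

test_that("validation re-closes small deviations and rejects bad rows", {
  d <- make_long()
  out <- validate_long(d, parts = c("sleep", "sb", "lpa", "mvpa"),
                       subject = "id", occasion = "occasion", kappa = 1440)
  expect_equal(out, d, ignore_attr = TRUE)

  d2 <- d
  d2$sleep[1] <- 599.2 # row sums to 1439.2
  expect_warning(
    out2 <- validate_long(d2, parts = c("sleep", "sb", "lpa", "mvpa"),
                          subject = "id", occasion = "occasion",
                          kappa = 1440),
    "re-closed")
  expect_equal(rowSums(out2[, c("sleep", "sb", "lpa", "mvpa")]),
               rep(1440, 4), ignore_attr = TRUE)
  expect_equal(attr(out2, "validation_report")$n_reclosed, 1L)

  d3 <- d
  d3$mvpa[2] <- 0
  expect_error(validate_long(d3, parts = c("sleep", "sb", "lpa", "mvpa"),
                             subject = "id", occasion = "occasion",
                             kappa = 1440), "mvpa")

  d4 <- d
  d4$sleep[1] <- 1200 # sum off by >5%
  expect_error(validate_long(d4, parts = c("sleep", "sb", "lpa", "mvpa"),
                             subject = "id", occasion = "occasion",
                             kappa = 1440), "deviate")

  d5 <- rbind(d, d[1, ])
  expect_error(validate_long(d5, parts = c("sleep", "sb", "lpa", "mvpa"),
                             subject = "id", occasion = "occasion",
                             kappa = 1440), "duplicate")

  expect_error(validate_long(d[, -3], parts = c("sleep", "sb", "lpa", "mvpa"),
                             subject = "id", occasion = "occasion",
                             kappa = 1440), "sleep")
})

test_that("olr columns append per record and respect the basis geometry", {
  d <- make_long()
  d[1, c("sleep", "sb", "lpa", "mvpa")] <- c(360, 360, 360, 360)
  o <- compute_olr(d, time_use_basis)
  expect_equal(unname(unlist(o[1, c("z1", "z2", "z3")])), c(0, 0, 0))
  d2 <- make_long()
  d2[1, c("sleep", "sb", "lpa", "mvpa")] <- c(584, 483, 294, 79)
  o2 <- compute_olr(d2, time_use_basis)
  expect_lt(max(abs(unlist(o2[1, c("z1", "z2", "z3")]) -
                      c(0.830, 0.940, 0.930))), 0.005)
  # coordinates under two bases are related by the change-of-basis rotation
  oalt <- compute_olr(d2, time_use_alt)
  Z1 <- as.matrix(o2[, c("z1", "z2", "z3")])
  Z2 <- as.matrix(oalt[, c("z1", "z2", "z3")])
  expect_equal(change_of_basis(Z1, time_use_basis, time_use_alt), Z2,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("stacking produces the one-hot long layout and inverts exactly", {
  d <- data.frame(id = "a", occasion = paste0("T", 1:4),
                  sleep = 580 + 1:4, sb = 470 - 1:4, lpa = rep(310, 4),
                  mvpa = rep(80, 4), zbmi = 0.3)
  o <- compute_olr(d, time_use_basis)
  st <- stack_olr(o)
  expect_equal(nrow(st), 12L) # 4 occasions x 3 coordinates
  expect_true(all(rowSums(st[, c("d1", "d2", "d3")]) == 1L))
  # predictors replicate unchanged within a record
  expect_equal(unname(table(st$zbmi)), 12L, ignore_attr = TRUE)
  back <- unstack_olr(st)
  expect_equal(back[, names(o)], o, ignore_attr = TRUE)
})

test_that("stacked row count scales as records times coordinates", {
  d <- make_fixture("loh_like", seed = 99)
  expect_equal(nrow(d), 241L * 5L)
  st <- stack_olr(compute_olr(d, time_use_basis))
  expect_equal(nrow(st), 241L * 5L * 3L)
  # the (subject, occasion) multiset is preserved with multiplicity D-1
  key <- paste(d$id, d$occasion)
  skey <- paste(st$id, st$occasion)
  expect_equal(sort(unique(skey)), sort(unique(key)))
  expect_true(all(table(skey) == 3L))
})
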