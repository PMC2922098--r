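# small helper: wrap a gene x whorl totals matrix as a classifiable flower
fake_flower <- function(totals, day = 5) {
  structure(lapply(1:4, function(w) {
    list(times = day, whorl = w,
         totals = matrix(totals[, w], 1, 6, dimnames = list(NULL, FLORAL_GENES)))
  }), class = "flower_trajectory")
}

test_that("the ABCDE map assigns organ identities from on/off patterns", {
  mk <- function(...) {
    m <- matrix(10, 6, 4, dimnames = list(FLORAL_GENES, NULL))
    on <- list(...)
    for (w in seq_along(on)) m[on[[w]], w] <- 1e3
    m
  }
  pat <- mk(c("AP1", "SEP"), c("AP1", "AP3", "PI", "SEP"),
            c("AP3", "PI", "AG", "SEP"), c("AG", "SHP", "SEP"))
  expect_identical(classify_organs(fake_flower(pat))$labels,
                   c("sepal", "petal", "stamen", "carpel"))
  # E loss means no floral organ regardless of the rest
  noE <- mk(c("AP1"), c("AP1", "AP3", "PI"), c("AG"), c("AG", "SHP"))
  expect_identical(classify_organs(fake_flower(noE))$labels, rep("none", 4))
  # B needs both AP3 and PI: AP3 alone does not make a petal
  halfB <- mk(c("AP1", "AP3", "SEP"), c("AP1", "SEP"),
              c("AP1", "PI", "SEP"), c("SEP"))
  expect_identical(classify_organs(fake_flower(halfB))$labels,
                   c("sepal", "sepal", "sepal", "none"))
  # A and C together match no organ program
  conflict <- mk(c("AP1", "AG", "SEP"), "SEP", "SEP", "SEP")
  expect_identical(classify_organs(fake_flower(conflict))$labels[1], "none")
})

test_that("signed mean relative error measures systematic bias", {
  x <- array(100, c(6, 4, 6))
  expect_equal(mean_relative_error(x, x), matrix(0, 6, 4), ignore_attr = TRUE)
  expect_equal(mean_relative_error(1.1 * x, x)[3, 2], 0.1)
  expect_equal(mean_relative_error(0.8 * x, x)[1, 1], -0.2)  # sign convention
  x0 <- x; x0[2, 2, 3] <- 0
  expect_error(mean_relative_error(x, x0), "zero")
  eps <- mean_relative_error(x, x0, na_on_zero = TRUE)
  expect_true(is.na(eps[2, 2]) && eps[1, 1] == 0)
})

test_that("the wild-type flower develops sepal, petal, stamen, carpel", {
  call <- classify_organs(simulate_flower())
  expect_identical(call$labels, c("sepal", "petal", "stamen", "carpel"))
})

test_that("B-gene knockouts convert petals to sepals and stamens to carpels", {
  wt <- floralfate:::wild_type_call()
  ap3 <- run_mutant(mutant_spec("knockout", "AP3"), wild_type = wt)
  expect_identical(ap3$call$labels, c("sepal", "sepal", "carpel", "carpel"))
  expect_setequal(ap3$changed_whorls, c(2L, 3L))
  # the knocked-out gene is gone at all times
  expect_lt(max(ap3$flower[[3]]$monomers[, "AP3"]), 1e-9)
  pi_ <- run_mutant(mutant_spec("knockout", "PI"), wild_type = wt)
  expect_identical(pi_$call$labels, ap3$call$labels)
})

test_that("C-gene perturbations reproduce the classical homeotic conversions", {
  wt <- floralfate:::wild_type_call()
  agko <- run_mutant(mutant_spec("knockout", "AG"), wild_type = wt)
  expect_identical(agko$call$labels, c("sepal", "petal", "petal", "sepal"))
  agoe <- run_mutant(mutant_spec("ectopic", "AG"), wild_type = wt)
  expect_identical(agoe$call$labels, c("carpel", "stamen", "stamen", "carpel"))
  # the pinned gene stays at its clamp level throughout
  expect_equal(unique(agoe$flower[[1]]$monomers[, "AG"]), 1e4)
})

test_that("the dimer-removal screen reproduces the predicted conversions", {
  scr <- dimer_knockout_screen()
  expect_identical(nrow(scr), 7L)
  expect_true(all(scr$altered))
  expect_identical(sum(scr$double_conversion), 5L)
  row <- function(d) scr[scr$dimer == d, ]
  expect_identical(unlist(row("AP3:PI")[, c("w1", "w2", "w3", "w4")], use.names = FALSE),
                   c("sepal", "sepal", "carpel", "carpel"))
  expect_identical(unlist(row("AP1:SEP")[, c("w1", "w2", "w3", "w4")], use.names = FALSE),
                   c("carpel", "stamen", "stamen", "carpel"))
  expect_identical(unlist(row("AG:AG")[, c("w1", "w2", "w3", "w4")], use.names = FALSE),
                   c("sepal", "petal", "petal", "sepal"))
  expect_identical(unlist(row("SEP:SEP")[, c("w1", "w2", "w3", "w4")], use.names = FALSE),
                   rep("none", 4))
  # ovule-identity surrogate: carpels persist but the D function collapses
  shp_row <- row("SHP:SEP")
  expect_identical(shp_row$n_changed, 0L)
  expect_true(shp_row$d_function_lost)
})

test_that("literature concordance scores four full matches and one partial", {
  lc <- literature_concordance()
  expect_identical(lc$n_full, 4L)
  expect_identical(lc$n_partial, 1L)
  ap3oe <- lc$results$ap3_ectopic
  expect_identical(ap3oe$status, "partial")
  expect_true(ap3oe$whorl_match[4])    # stamens in whorl 4 as observed
  expect_false(ap3oe$whorl_match[1])   # model predicts petals in whorl 1
  expect_identical(lc$results$pi_knockout$labels, lc$results$ap3_knockout$labels)
})

test_that("input validation of the experiment layer", {
  expect_error(mutant_spec("knockout"), "needs a target")
  expect_error(mutant_spec("dimer_removal", "AP1:AP9"), "unknown dimer")
  expect_error(gamma_robustness(factor = 1), "> 1")
})
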