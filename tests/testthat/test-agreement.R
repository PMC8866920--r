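test_that("Dice coefficient matches hand arithmetic and its conventions", {
  a <- array(c(1, 1, 0, 0), c(1, 2, 2))
  b <- array(c(1, 0, 1, 0), c(1, 2, 2))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, 1 - a), 0)
  expect_equal(dice(a, b), 0.5)  # |A|=|B|=2, one shared voxel
  expect_equal(dice(a, b), dice(b, a))
  # simultaneous flips leave the overlap unchanged
  expect_equal(dice(a[, 2:1, ], b[, 2:1, ]), dice(a, b))
  # both empty -> perfect agreement on absence
  z <- array(0, c(2, 2, 2))
  expect_equal(dice(z, z), 1)
  expect_error(dice(a, array(0, c(2, 2, 2))), "shape")
})

test_that("multiclass Dice reports per-class and pooled union values", {
  ph <- make_phantom(tiny_spec(seed = 9))
  lab <- ph$labels$labels
  md <- multiclass_dice(lab, lab)
  expect_true(all(md == 1, na.rm = TRUE))
  # swapping classes 1 and 2 keeps the pooled DSC at 1
  swapped <- lab
  swapped[lab == 1L] <- 2L
  swapped[lab == 2L] <- 1L
  ms <- multiclass_dice(lab, swapped)
  expect_equal(unname(ms[["pooled"]]), 1)
  expect_lt(ms[["class1"]], 1)
  expect_lt(ms[["class2"]], 1)
  # a class absent from both maps is NA
  both <- lab; both[both == 4L] <- 0L
  m4 <- multiclass_dice(both, both)
  expect_true(is.na(m4[["class4"]]))
  expect_equal(unname(m4[["class1"]]), 1)
})

test_that("Pearson correlation matches the closed form with a p-value", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  pr <- pearson(x, y)
  expect_equal(pr$r, 0.9819805, tolerance = 1e-6)
  expect_true(pr$p >= 0 && pr$p <= 1)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  # invariance under positive affine transforms
  set.seed(14)
  u <- rnorm(20); v <- rnorm(20)
  expect_equal(pearson(2 * u + 3, v)$r, pearson(u, v)$r)
  expect_error(pearson(c(1, 1, 1), y), "variance")
  expect_error(pearson(1:2, 2:1), "at least 3")
})

test_that("ICC(2,1) matches an aov mean-squares oracle and penalizes offsets", {
  set.seed(15)
  x <- rnorm(12, 50, 10)
  y <- x + rnorm(12, 2, 3)
  # oracle: mean squares from a two-way anova decomposition
  icc_oracle <- function(x, y) {
    n <- length(x)
    df <- data.frame(v = c(x, y),
                     subj = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(1:2, each = n)))
    ms <- suppressWarnings(anova(aov(v ~ subj + rater, data = df))[["Mean Sq"]])
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
  }
  expect_equal(icc(x, y), icc_oracle(x, y), tolerance = 1e-10)
  expect_equal(icc(x, x), 1)
  # constant offset: ICC < Pearson r = 1
  y_off <- x + 10
  expect_equal(pearson(x, y_off)$r, 1)
  expect_lt(icc(x, y_off), 1)
  expect_equal(icc(x, y_off), icc_oracle(x, y_off), tolerance = 1e-10)
  # independent pairs have ICC near zero
  set.seed(16)
  a <- rnorm(50); b <- rnorm(50)
  expect_lt(abs(icc(a, b)), 0.3)
  expect_warning(ident <- icc(rep(3, 5), rep(3, 5)), "identical")
  expect_equal(ident, 1)
})

test_that("Bland-Altman analysis takes manual-minus-auto differences", {
  ba0 <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(ba0$bias, 0); expect_equal(ba0$sd, 0)
  ba <- bland_altman(c(10, 12), c(9, 10))
  expect_equal(ba$bias, 1.5)
  expect_equal(ba$sd, 0.7071068, tolerance = 1e-6)
  expect_equal(ba$loa_high - ba$loa_low, 3.92 * ba$sd)
  # bias is exactly the difference of means; sign flips when swapped
  set.seed(17)
  m <- rnorm(15, 100, 10); a <- rnorm(15, 95, 10)
  bam <- bland_altman(m, a)
  expect_equal(bam$bias, mean(m) - mean(a))
  expect_equal(bland_altman(a, m)$bias, -bam$bias)
  expect_error(bland_altman(1:3, 1:4), "paired")
})

test_that("agreement reports assemble the summary-row layout", {
  set.seed(18)
  manual <- rnorm(10, 130, 20)
  auto <- manual - rnorm(10, 4, 2)
  dsc <- runif(10, 0.9, 0.99)
  rep <- agreement_report("VV", dsc, manual, auto)
  expect_equal(rep$dsc_mean, mean(dsc))
  expect_equal(rep$bias, mean(manual - auto))
  # limits of agreement bracket the bias symmetrically
  expect_equal(rep$loa_high - rep$bias, rep$bias - rep$loa_low)
  expect_match(rep$table_row$DSC, "^0\\.9. ± 0\\.0.$")
  expect_identical(rep$table_row$measurement, "VV")
  expect_error(agreement_report("VV", c(1.2, 0.5), manual[1:2], auto[1:2]),
               "DSC")
})

test_that("evaluating predictions against themselves is perfect agreement", {
  co <- tiny_cohort(4, seed = 19)
  labs <- lapply(co, function(cs) cs$thin$labels)
  ev <- evaluate_pairs(labs, labs)
  expect_true(all(ev$per_case$dsc_pooled == 1))
  expect_true(all(ev$per_case$dsc_brain == 1))
  expect_equal(ev$summary$VV$bias, 0)
  expect_equal(ev$summary$ICV$bias, 0)
  expect_equal(ev$summary$VV$dsc_mean, 1)
  # volumes vary across cases, so correlation is defined and perfect
  expect_equal(ev$summary$VV$pearson_r, 1)
  expect_equal(ev$summary$VV$icc, 1)
})
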