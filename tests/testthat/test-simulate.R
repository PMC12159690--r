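test_that("cohort simulation is deterministic given a seed", {
  spec <- small_spec(15, seed = 42)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$uptake, b$uptake)
  expect_identical(a$covariates, b$covariates)
  c2 <- simulate_cohort(spec, seed = 43)
  expect_false(identical(a$uptake, c2$uptake))
})

test_that("sample moments recover the spec at large n", {
  spec <- cohort_spec(10000, n_regions = 8,
                      block_structure = list(list(regions = 1:4, rho = 0.6)),
                      between_block_correlation = 0.1,
                      region_means = 2, region_sds = 0.3,
                      age_slope = 0, sex_offset = 0, seed = 7)
  hc <- simulate_cohort(spec)
  se <- 0.3 / sqrt(10000)
  expect_true(all(abs(colMeans(hc$uptake) - 2) < 3 * se))
  cc <- cor(hc$uptake[, 1:4])
  expect_true(all(abs(cc[lower.tri(cc)] - 0.6) < 0.03))
  expect_true(all(abs(apply(hc$uptake, 2, sd) - 0.3) < 0.02))
})

test_that("age and sex effects enter the mean surface linearly", {
  spec <- cohort_spec(4000, n_regions = 4, block_structure = list(),
                      between_block_correlation = 0,
                      region_means = 1, region_sds = 0.05,
                      age_slope = -0.01, sex_offset = 0.2, seed = 3)
  hc <- simulate_cohort(spec)
  fit <- lm(hc$uptake[, 1] ~ hc$covariates$age + hc$covariates$sex)
  expect_equal(unname(coef(fit)[2]), -0.01, tolerance = 0.02)
  expect_equal(unname(coef(fit)[3]), 0.2, tolerance = 0.05)
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(1), "n_subjects")
  expect_error(small_spec(10, m = 6, rho = 1.4), "\\[-1, 1\\]")
  expect_error(cohort_spec(10, n_regions = 4, region_sds = c(0.1, -1, 0.1, 0.1),
                           block_structure = list()), "positive")
})

test_that("an infeasible correlation overlay is repaired to PSD with a warning", {
  # two overlapping blocks with contradictory correlations force repair
  expect_warning(
    spec <- cohort_spec(10, n_regions = 6, between_block_correlation = -0.3,
                        block_structure = list(list(regions = 1:4, rho = 0.9),
                                               list(regions = 3:6, rho = -0.8)),
                        region_means = 1, region_sds = 0.1),
    "repaired")
  ev <- eigen(spec$correlation, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-10)
  expect_true(attr(spec$correlation, "repaired"))
})

test_that("magnitude-zero patients match the control distribution", {
  spec <- small_spec(200, m = 12, seed = 5)
  pert <- perturbation_spec(1:6, magnitude = 0)
  pats <- simulate_patients(spec, pert, 200, seed = 6)
  hc <- simulate_cohort(spec)
  # same marginal mean/sd within Monte-Carlo error
  for (j in c(1, 6, 12)) {
    expect_equal(mean(pats$uptake[, j]), mean(hc$uptake[, j]), tolerance = 0.06)
    expect_equal(sd(pats$uptake[, j]), sd(hc$uptake[, j]), tolerance = 0.05)
  }
})

test_that("perturbation errors on bad region sets", {
  expect_error(perturbation_spec(integer(0), magnitude = 2), "empty")
  spec <- small_spec(10, m = 6)
  expect_error(simulate_patients(spec, perturbation_spec(5:9), 3), "outside")
})

test_that("strengthen and weaken displace along the leading / trailing axes", {
  spec <- small_spec(50, m = 10, seed = 2)
  d_s <- molpert:::perturbation_delta(spec, perturbation_spec(1:5, "strengthen", 4))
  d_w <- molpert:::perturbation_delta(spec, perturbation_spec(1:5, "weaken", 4))
  S <- (spec$correlation * tcrossprod(spec$region_sds))[1:5, 1:5]
  e <- eigen(S, symmetric = TRUE)
  # alignment with the intended eigenvector
  align <- function(d, v) abs(sum(d[1:5] * v)) / sqrt(sum(d[1:5]^2))
  expect_gt(align(d_s, e$vectors[, 1]), 0.999)
  expect_gt(align(d_w, e$vectors[, 5]), 0.999)
  expect_true(all(d_s[6:10] == 0))
  # magnitude scales the displacement linearly
  d_s2 <- molpert:::perturbation_delta(spec, perturbation_spec(1:5, "strengthen", 8))
  expect_equal(d_s2, 2 * d_s, tolerance = 1e-12)
})

test_that("expected patient SED is monotone in perturbation magnitude", {
  spec <- small_spec(40, m = 12, seed = 9)
  hc <- simulate_cohort(spec)
  ref <- reference_network(hc$uptake, hc$covariates)
  mags <- c(0, 2, 5)
  mean_sed <- sapply(seq_along(mags), function(k) {
    s <- sapply(1:10, function(rep) {
      pats <- simulate_patients(spec, perturbation_spec(1:6, "weaken", mags[k]),
                                5, seed = 100 * k + rep)
      devs <- suppressWarnings(predict(ref, pats$uptake, pats$covariates))
      mean(vapply(lapply(devs, threshold_deviation), sed, numeric(1)))
    })
    mean(s)
  })
  expect_true(all(diff(mean_sed) > 0))
})

test_that("opposite perturbation directions give opposite-signed block deviations", {
  spec <- small_spec(60, m = 12, seed = 13)
  hc <- simulate_cohort(spec)
  ref <- reference_network(hc$uptake, hc$covariates)
  block_z <- function(direction) {
    pats <- simulate_patients(spec, perturbation_spec(1:6, direction, 5), 15, seed = 77)
    devs <- suppressWarnings(predict(ref, pats$uptake, pats$covariates))
    mean(vapply(devs, function(d) {
      zb <- d$z[1:6, 1:6]; mean(zb[lower.tri(zb)])
    }, numeric(1)))
  }
  expect_gt(block_z("strengthen"), 0)
  expect_lt(block_z("weaken"), 0)
})

test_that("longitudinal identity holds at full stability and no noise or shrink", {
  spec <- small_spec(20, m = 8, seed = 4)
  lp <- simulate_longitudinal(spec, perturbation_spec(1:4, magnitude = 3),
                              10, longitudinal_spec(1, 1, 0), seed = 5)
  expect_identical(rownames(lp$baseline), rownames(lp$followup))
  expect_equal(lp$baseline, lp$followup, tolerance = 1e-12)
})

test_that("treatment_shrink = 0 returns follow-up to the control null level", {
  spec <- small_spec(60, m = 12, seed = 21)
  hc <- simulate_cohort(spec)
  ref <- reference_network(hc$uptake, hc$covariates)
  lp <- simulate_longitudinal(spec, perturbation_spec(1:6, "weaken", 5), 25,
                              longitudinal_spec(0.7, 0, 0.01), seed = 6)
  held <- simulate_cohort(spec, seed = 99)
  sed_of <- function(vals, cov) {
    devs <- suppressWarnings(predict(ref, vals, cov))
    vapply(lapply(devs, threshold_deviation), sed, numeric(1))
  }
  s_base <- sed_of(lp$baseline, lp$covariates)
  s_fup <- sed_of(lp$followup, lp$covariates)
  s_ctrl <- sed_of(held$uptake[1:25, ], held$covariates[1:25, ])
  expect_gt(mean(s_base), 3 * mean(s_ctrl))           # baseline clearly perturbed
  expect_lt(mean(s_fup), mean(s_ctrl) + 2 * sd(s_ctrl))  # follow-up back to null level
})

test_that("longitudinal spec validates its parameters", {
  expect_error(longitudinal_spec(stability_rho = 1.2), "stability_rho")
  expect_error(longitudinal_spec(treatment_shrink = -0.1), "treatment_shrink")
  spec <- small_spec(10, m = 6)
  expect_error(
    simulate_longitudinal(spec, perturbation_spec(1:3, mode = "rescale"),
                          5, longitudinal_spec()), "axis_shift")
})
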