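# Frozen cross-implementation oracle: A^2 for this fixed 20-point sample was
# computed independently with the scipy.stats normal-CDF formulation
# (uncorrected statistic 0.49003615412539503, case-3 p 0.19589483648748426).
.ad_fixture <- c(10.609434, 7.920032, 11.500902, 11.881129, 6.09793,
                 7.395641, 10.255681, 9.367515, 9.966398, 8.293912,
                 11.758796, 11.555584, 10.132061, 12.254482, 10.935019,
                 8.281415, 10.737502, 8.082235, 11.756901, 9.900148)

test_that("Anderson-Darling matches the frozen reference and its contracts", {
  res <- anderson_darling(.ad_fixture)
  expect_equal(res$statistic, 0.49003615412539503, tolerance = 1e-6)
  expect_equal(res$p.value, 0.19589483648748426, tolerance = 1e-6)

  expect_error(anderson_darling(rnorm(5)), "n >= 8")
  expect_error(anderson_darling(rep(3, 20)), "zero variance")
  expect_error(anderson_darling(c(rnorm(10), NA)), "non-finite")

  # affine invariance of the statistic
  set.seed(201)
  for (i in 1:10) {
    x <- rnorm(60)
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 5)
    expect_equal(anderson_darling(a * x + b)$statistic,
                 anderson_darling(x)$statistic, tolerance = 1e-9)
  }
})

test_that("Anderson-Darling has power against an exponential sample", {
  set.seed(202)
  rejections <- vapply(1:20, function(i) {
    anderson_darling(rexp(500))$p.value < 0.01
  }, logical(1))
  expect_gte(mean(rejections), 0.99)
})

test_that("normality report favors ilr for data Gaussian in balance space", {
  sbp <- default_ionome_sbp()
  # strongly skewed in raw space: wide balance dispersion
  groups <- list(
    group_spec("a", c(1.2, -0.5, 1.8, 1.0), diag(0.9^2, 4), 220),
    group_spec("b", c(0.2, 0.6, 1.2, 0.2), diag(0.9^2, 4), 220))
  sim <- simulate_ionomes(simulation_spec(sbp, groups, seed = 301))
  rep_ <- normality_by_representation(sim$table, sbp, alpha = 0.01)
  agg <- rep_$aggregate
  frac <- function(r) agg$fraction_normal[agg$representation == r]
  expect_gte(frac("ilr"), 0.8)
  expect_lt(frac("raw"), frac("ilr"))
  expect_identical(unique(rep_$tests$representation[rep_$tests$normal |
                                                      !rep_$tests$normal]),
                   c("raw", "log", "alr", "ilr"))
  expect_identical(nrow(agg), 4L)

  # single pooled group, single-variable degenerate shape
  one <- composition_table(matrix(exp(rnorm(40)), 20, 2), kappa = 1)
  r1 <- normality_by_representation(one, representations = "raw")
  expect_identical(nrow(r1$tests), 2L)

  # all-equal compositions surface as warnings, not failures
  flat <- composition_table(matrix(1, 12, 3), kappa = 1)
  w <- testthat::capture_warnings(
    rflat <- normality_by_representation(flat, representations = "raw"))
  expect_true(any(grepl("zero variance", w)))
  expect_identical(nrow(rflat$tests), 0L)
  expect_true(is.na(rflat$aggregate$fraction_normal))
  # small groups are skipped with a warning
  tiny <- composition_table(matrix(exp(rnorm(12)), 4, 3), kappa = 1,
                            group = c("a", "a", "b", "b"))
  w2 <- testthat::capture_warnings(
    normality_by_representation(tiny, representations = "raw"))
  expect_true(any(grepl("skipped", w2)))
})

test_that("scale dependency: spurious correlation appears in raw closed data", {
  set.seed(203)
  # independent log-normal g/kg concentrations embedded in dry matter via a
  # filling value; re-closing the nutrient subcomposition to its own sum
  # manufactures negative correlation among dominant parts
  conc <- cbind(N = rlnorm(200, 3, 0.4), P = rlnorm(200, 1, 0.4),
                K = rlnorm(200, 2.5, 0.4), Ca = rlnorm(200, 2.5, 0.4))
  tab <- composition_table(cbind(conc, Fv = 1000 - rowSums(conc)),
                           kappa = 1000, unit = "g/kg", close = FALSE)
  rep_ <- scale_dependency(tab, scales = list(
    list(kappa = 1000, label = "dry_matter"),
    list(kappa = 100, parts = c("N", "P", "K", "Ca"), label = "nutrient_sum")))
  expect_lt(min(rep_$matrices$nutrient_sum), -0.3)
  expect_true(any(rep_$delta > 0.1))

  # identical scale twice: identical matrices
  rep_same <- scale_dependency(tab, scales = list(list(kappa = 100),
                                                  list(kappa = 100)))
  expect_equal(rep_same$matrices[[1]], rep_same$matrices[[2]],
               tolerance = 1e-15)
  expect_false(any(rep_same$sign_flip))

  # 2-part closed data: exactly -1 off-diagonal under any sum closure
  two <- composition_table(cbind(x = rlnorm(50), y = rlnorm(50)), kappa = 100)
  rep2 <- scale_dependency(two, scales = list(list(kappa = 100),
                                              list(kappa = 1)))
  expect_equal(rep2$matrices[[1]]["x", "y"], -1, tolerance = 1e-12)

  expect_error(scale_dependency(tab, scales = list(list(kappa = 1))),
               "at least two")
  expect_error(scale_dependency(table_subset(tab, 1:2),
                                scales = list(list(kappa = 1),
                                              list(kappa = 2))),
               "insufficient data")
})

test_that("log-ratio correlation matrices are identical across closure scales", {
  set.seed(204)
  tab <- random_table(100, 5)
  sbp <- random_sbp(paste0("p", 1:5))
  for (repn in c("clr", "ilr")) {
    rep_ <- scale_dependency(tab,
                             scales = list(list(kappa = 100),
                                           list(kappa = 1),
                                           list(kappa = 1000)),
                             representation = repn, sbp = sbp)
    expect_lt(max(rep_$delta), 1e-12)
    expect_false(any(rep_$sign_flip))
  }
})

test_that("robust outliers: implanted point flagged, preconditions enforced", {
  set.seed(205)
  x <- MASS::mvrnorm(150, rep(0, 3), diag(3))
  x[1, ] <- c(10, -10, 10)  # ~10 robust SDs out
  om <- robust_outliers(x, alpha = 0.01, seed = 1)
  expect_true(om$flagged[1])
  expect_equal(om$cutoff, qchisq(0.99, 3))
  expect_lt(mean(om$flagged[-1]), 0.1)

  expect_error(robust_outliers(x[1:4, ], alpha = 0.01), "n > dimension")
  sing <- cbind(x[, 1], x[, 1], x[, 2])
  expect_error(robust_outliers(sing, seed = 1), "singular|collinear|degenerate")
})

test_that("outlier flags are invariant to the SBP used for ilr coordinates", {
  set.seed(206)
  sbp1 <- default_ionome_sbp()
  groups <- list(group_spec("a", c(0.5, 0.2, 1.5, 0.8), diag(0.2^2, 4), 120))
  sim <- simulate_ionomes(simulation_spec(sbp1, groups, seed = 401))
  labels <- attr(sim$table, "parts")
  sbp2 <- random_sbp(labels)
  m1 <- representation_matrix(sim$table, sbp1, "ilr")
  m2 <- representation_matrix(sim$table, sbp2, "ilr")
  om1 <- robust_outliers(m1, alpha = 0.01, seed = 5)
  om2 <- robust_outliers(m2, alpha = 0.01, seed = 5)
  # orthonormal re-expression: identical distances up to estimator determinism
  expect_identical(om1$flagged, om2$flagged)
  expect_equal(om1$distance, om2$distance, tolerance = 1e-6)
})

test_that("screen_outliers works per group and returns aligned masks", {
  set.seed(207)
  sbp <- default_ionome_sbp()
  groups <- list(group_spec("a", c(0, 0, 1, 0), diag(0.2^2, 4), 120),
                 group_spec("b", c(1, 0.5, 2, 1), diag(0.2^2, 4), 120))
  sim <- simulate_ionomes(simulation_spec(sbp, groups, seed = 402))
  mask <- screen_outliers(sim$table, sbp, alpha = 0.01, seed = 3)
  expect_identical(mask$sample_id, sim$table$sample_id)
  expect_setequal(unique(mask$group), c("a", "b"))
  expect_lt(mean(mask$flagged), 0.15)
  pooled <- screen_outliers(sim$table, sbp, alpha = 0.01, pool = TRUE, seed = 3)
  expect_identical(unique(pooled$group), "all")
})
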