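test_that("Aitchison distance: identity, SBP invariance, clr oracle", {
  labels <- paste0("p", 1:5)
  set.seed(101)
  a <- random_comp(5, labels = labels)
  expect_equal(aitchison_distance(a, a, random_sbp(labels)), 0)

  for (i in 1:10) {
    a <- random_comp(5, labels = labels); b <- random_comp(5, labels = labels)
    s1 <- random_sbp(labels); s2 <- random_sbp(labels)
    d1 <- aitchison_distance(a, b, s1)
    expect_equal(d1, aitchison_distance(a, b, s2), tolerance = 1e-10)
    # independent route: Euclidean distance between clr vectors
    expect_equal(d1, sqrt(sum((clr(a) - clr(b))^2)), tolerance = 1e-10)
    # and closure-scale invariance
    a2 <- closure(as.numeric(a), kappa = 1, labels = labels)
    b2 <- closure(as.numeric(b), kappa = 1000, labels = labels)
    expect_equal(aitchison_distance(a2, b2, s1), d1, tolerance = 1e-10)
  }
  expect_error(aitchison_distance(a, random_comp(4), table1_sbp()),
               "share part labels")
})

test_that("Aitchison norm equals distance to the barycenter", {
  labels <- paste0("p", 1:6)
  eq <- composition(rep(1, 6), labels = labels)
  expect_equal(aitchison_norm(eq), 0)
  set.seed(102)
  sbp <- random_sbp(labels)
  for (i in 1:10) {
    a <- random_comp(6, labels = labels)
    expect_equal(aitchison_norm(a, sbp), aitchison_distance(a, eq, sbp),
                 tolerance = 1e-12)
  }
  # 2-part: norm is the magnitude of the single balance
  np <- composition(c(N = 2.50, P = 0.15))
  expect_equal(round(aitchison_norm(np), 2), 1.99)
})

test_that("log-Euclidean bias decomposition holds on 1000 random pairs", {
  set.seed(103)
  labels <- paste0("p", 1:5)
  for (i in 1:1000) {
    a <- random_comp(5, labels = labels)
    b <- random_comp(5, labels = labels)
    rep_ <- log_euclidean_bias(a, b)
    lhs <- rep_$log_euclidean^2
    rhs <- rep_$aitchison^2 + rep_$bias_term
    expect_lt(abs(lhs - rhs), 1e-10 * max(lhs, 1e-12))
    expect_gte(rep_$log_euclidean, rep_$aitchison)
  }
})

test_that("bias vanishes iff geometric means agree; scales must match", {
  labels <- paste0("p", 1:4)
  a <- composition(exp(c(0.3, -0.1, 0.2, -0.4)), labels = labels, kappa = 1)
  expect_equal(log_euclidean_bias(a, a)$aitchison, 0)
  expect_equal(log_euclidean_bias(a, a)$bias_term, 0)

  # construct b closed to the same kappa with the same geometric mean:
  # perturb logs by t * delta (delta zero-sum, so g is conserved) and pick
  # the nonzero t at which the parts again sum to 1
  la <- log(as.numeric(a))
  delta <- c(0.2, -0.3, 0.25, -0.15)
  f <- function(t) sum(exp(la + t * delta)) - 1
  tmin <- stats::optimize(function(t) sum(exp(la + t * delta)),
                          interval = c(-10, 10))$minimum
  t1 <- stats::uniroot(f, c(tmin + 1e-9, 50), tol = 1e-14)$root
  if (abs(t1) < 1e-6) t1 <- stats::uniroot(f, c(-50, tmin - 1e-9),
                                           tol = 1e-14)$root
  b <- composition(exp(la + t1 * delta), labels = labels, kappa = 1)
  expect_equal(geomean(as.numeric(b)), geomean(as.numeric(a)),
               tolerance = 1e-10)
  rep_ <- log_euclidean_bias(a, b, ids = c("a", "b"))
  expect_gt(rep_$aitchison, 0)
  expect_equal(rep_$log_euclidean, rep_$aitchison, tolerance = 1e-10)

  mixed <- closure(as.numeric(a), kappa = 1000, labels = labels)
  expect_error(log_euclidean_bias(a, mixed), "different kappas")
  # explicit re-closure resolves the mixed scales
  expect_equal(log_euclidean_bias(a, mixed, kappa = 1)$aitchison, 0,
               tolerance = 1e-12)
})

test_that("epsilon depends on the closure choice while Aitchison does not", {
  # a common multiplicative rescaling (kappa = 100 -> 1000) cancels in log
  # differences, so epsilon is unchanged by the kappa magnitude alone ...
  set.seed(104)
  labels <- paste0("p", 1:5)
  a <- random_comp(5, labels = labels); b <- random_comp(5, labels = labels)
  r100 <- log_euclidean_bias(a, b, kappa = 100)
  r1000 <- log_euclidean_bias(a, b, kappa = 1000)
  expect_equal(r100$aitchison, r1000$aitchison, tolerance = 1e-10)
  expect_equal(r100$log_euclidean, r1000$log_euclidean, tolerance = 1e-10)

  # ... but the choice of closure TYPE does matter: the same five nutrient
  # profiles expressed per unit dry matter (varying totals, Fv embedding)
  # versus re-closed to their own sum give different epsilons, while the
  # Aitchison distance over the five parts is identical in both.
  adm <- c(N = 28, P = 2.2, K = 14, Ca = 9, Mg = 2.4)   # g/kg dry matter
  bdm <- c(N = 16, P = 1.1, K = 11, Ca = 14, Mg = 3.1)
  eps_dm <- sqrt(sum((log(adm) - log(bdm))^2))
  ac <- closure(adm, kappa = 100, labels = names(adm))
  bc <- closure(bdm, kappa = 100, labels = names(bdm))
  rsum <- log_euclidean_bias(ac, bc)
  expect_equal(rsum$aitchison,
               sqrt(sum((clr(composition(adm)) - clr(composition(bdm)))^2)),
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(eps_dm, rsum$log_euclidean,
                                tolerance = 1e-6)))
  # the Eq.-5 decomposition holds on the dry-matter scale too
  bias_dm <- 5 * (log(geomean(adm) / geomean(bdm)))^2
  expect_equal(eps_dm^2, rsum$aitchison^2 + bias_dm, tolerance = 1e-10)
})

test_that("Aitchison distance satisfies metric axioms and perturbation invariance", {
  set.seed(105)
  labels <- paste0("p", 1:5)
  sbp <- random_sbp(labels)
  for (i in 1:15) {
    a <- random_comp(5, labels = labels)
    b <- random_comp(5, labels = labels)
    cc <- random_comp(5, labels = labels)
    dab <- aitchison_distance(a, b, sbp)
    expect_equal(dab, aitchison_distance(b, a, sbp), tolerance = 1e-12)
    expect_lte(aitchison_distance(a, cc, sbp),
               dab + aitchison_distance(b, cc, sbp) + 1e-10)
    # perturbation: multiply both by a positive vector, re-close
    pert <- exp(rnorm(5))
    ap <- closure(as.numeric(a) * pert, kappa = 100, labels = labels)
    bp <- closure(as.numeric(b) * pert, kappa = 100, labels = labels)
    d2 <- aitchison_distance(ap, bp, sbp)
    expect_equal(d2, dab, tolerance = 1e-10)
  }
})

test_that("pairwise_distances matches the naive pair loop and Eq.-5 order", {
  set.seed(106)
  tab <- random_table(12, 5, group = rep(c("g1", "g2"), each = 6))
  sbp <- random_sbp(paste0("p", 1:5))
  pd <- pairwise_distances(tab, sbp, metric = "both")
  expect_equal(diag(pd$aitchison), rep(0, 12), ignore_attr = TRUE)
  expect_equal(pd$aitchison, t(pd$aitchison))

  for (i in 1:5) {
    pr <- sort(sample(12, 2))
    d <- aitchison_distance(table_row(tab, pr[1]), table_row(tab, pr[2]), sbp)
    expect_equal(pd$aitchison[pr[1], pr[2]], d, tolerance = 1e-12)
    rep_ <- log_euclidean_bias(table_row(tab, pr[1]), table_row(tab, pr[2]))
    expect_equal(pd$log_euclidean[pr[1], pr[2]], rep_$log_euclidean,
                 tolerance = 1e-12)
  }
  expect_true(all(pd$log_euclidean >= pd$aitchison - 1e-12))

  same <- composition_table(matrix(rep(c(2, 3, 5), each = 4), nrow = 4),
                            kappa = 10)
  pd0 <- pairwise_distances(same, metric = "aitchison")
  expect_equal(max(abs(pd0$aitchison)), 0, tolerance = 1e-12)
})

test_that("distance summaries and writers produce the declared layouts", {
  set.seed(107)
  tab <- random_table(14, 5, group = rep(c("a", "b"), each = 7))
  sbp <- random_sbp(paste0("p", 1:5))
  ds <- distance_summary(tab, sbp)
  expect_setequal(names(ds),
                  c("group", "metric", "n_pairs", "q25", "median", "q75"))
  expect_identical(nrow(ds), 4L)  # 2 groups x 2 metrics
  expect_true(all(ds$n_pairs == choose(7, 2)))
  # within each group the log-Euclidean median dominates the Aitchison median
  for (g in c("a", "b")) {
    expect_gte(ds$median[ds$group == g & ds$metric == "log_euclidean"],
               ds$median[ds$group == g & ds$metric == "aitchison"])
  }

  pd <- pairwise_distances(tab, sbp, metric = "both")
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_distance_long(pd, f1)
  long <- utils::read.csv(f1)
  expect_identical(nrow(long), 91L)  # choose(14, 2)
  expect_setequal(names(long),
                  c("id_a", "id_b", "aitchison", "log_euclidean", "bias_term"))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_distance_matrix(pd, f2)
  sq <- utils::read.csv(f2, check.names = FALSE)
  expect_identical(dim(sq), c(14L, 15L))
})
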