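# Screening statistics: oracles frozen from closed forms and exhaustive
# enumeration.

test_that("z_factor reproduces the closed form and flags degeneracy", {
  set.seed(1)
  zr <- z_factor(rnorm(2000, 1, 0.1), rnorm(2000, 0, 0.1))
  expect_equal(zr$z,
               1 - 3 * (zr$sd_p + zr$sd_n) / abs(zr$mu_p - zr$mu_n),
               tolerance = 1e-12)
  expect_lt(abs(zr$z - 0.4), 0.03)
  # exact construction: mu 1 / 0, sd 0.1 / 0.1 -> Z = 0.4
  expect_equal(z_factor(1 + c(-0.1, 0, 0.1), c(-0.1, 0, 0.1))$z, 0.4,
               tolerance = 1e-12)
  expect_equal(z_factor(c(1, 1, 1), c(0, 0, 0))$z, 1)
  same <- c(0.5, 0.5, 0.5)
  zd <- z_factor(same, same)
  expect_true(zd$undefined)
  expect_equal(zd$z, -Inf)
})

test_that("z_factor is monotone in separation and in spread", {
  base <- function(mu, s) list(p = mu + s * scale(rnorm(50)), n = s *
                                 scale(rnorm(50)))
  set.seed(2)
  zs <- vapply(c(0.5, 1, 2, 4), function(mu) {
    d <- base(mu, 0.1)
    z_factor(d$p, d$n)$z
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
  zspread <- vapply(c(0.05, 0.1, 0.2), function(s) {
    set.seed(3)
    z_factor(1 + s * scale(rnorm(50)), s * scale(rnorm(50)))$z
  }, numeric(1))
  expect_true(all(diff(zspread) < 0))
})

test_that("hit calling matches direct construction and the normal tail", {
  ref <- rep(c(0.9, 1, 1.1), 10)
  # all wells at the median: no hits
  hc0 <- call_hits(rep(1, 20), ref)
  expect_equal(sum(hc0$calls$hit), 0)
  # exactly one well beyond 4 reference SDs
  s <- sd(ref)
  hc1 <- call_hits(c(rep(1, 9), 1 + 4 * s), ref)
  expect_equal(sum(hc1$calls$hit), 1)
  expect_equal(which(hc1$calls$hit), 10L)
  expect_equal(hc1$calls$direction[10], "up")
  # null rate ~ 2*Phi(-3) for normal scores
  set.seed(4)
  null <- rnorm(20000)
  hc <- call_hits(null, null, k = 3)
  p0 <- 2 * pnorm(-3)
  se <- sqrt(p0 * (1 - p0) / 20000)
  expect_lt(abs(mean(hc$calls$hit) - p0), 3 * se)
  expect_lt(mean(hc$calls$hit), 0.01)
  # degenerate reference
  expect_warning(hcd <- call_hits(1:5, rep(1, 10)), "degenerate")
  expect_true(hcd$degenerate)
})

test_that("replicate power follows the geometric closed form", {
  # simulation vs 1-(1-p)^n within 3 Monte-Carlo SEs, p = Phi(d-k)
  pr <- replicate_power("normal", d = 2, k = 3, power_target = 0.85,
                        n_max = 15, n_sim = 4000, seed = 5)
  p1 <- pnorm(2 - 3)
  for (n in c(1, 5, 11, 15)) {
    expected <- 1 - (1 - p1)^n
    se <- sqrt(expected * (1 - expected) / 4000)
    expect_lt(abs(pr$power[n] - expected), 3 * se + 1e-9)
  }
  expect_true(all(diff(pr$power_monotone) >= 0))
  # analytic oracle boundaries: n = 11 at d=2, n = 1 at d=6
  pa <- replicate_power("normal", d = 2, k = 3, power_target = 0.85,
                        n_max = 30, method = "analytic")
  expect_equal(pa$n_min, 11L)
  pa6 <- replicate_power("normal", d = 6, k = 3, power_target = 0.85,
                         n_max = 5, method = "analytic")
  expect_equal(pa6$n_min, 1L)
  # d = 0, two-sided: p = 2*Phi(-3), minimal n = 702
  pa0 <- replicate_power("normal", d = 0, k = 3, power_target = 0.85,
                         n_max = 800, directional = FALSE,
                         method = "analytic")
  expect_equal(pa0$n_min, 702L)
  # unreachable target is reported, not an error
  pu <- replicate_power("normal", d = 0, k = 3, power_target = 0.85,
                        n_max = 5, n_sim = 200, seed = 6)
  expect_false(pu$reached)
  # empirical nulls are accepted and the analytic path refuses them
  emp <- rnorm(500)
  pe <- replicate_power(emp, d = 6, k = 3, n_max = 3, n_sim = 500,
                        seed = 7)
  expect_equal(pe$n_min, 1L)
  expect_error(replicate_power(emp, d = 2, method = "analytic"),
               "normal null")
})

test_that("group comparisons: exact U enumeration, Welch, degeneracies", {
  # {1,2,3} vs {4,5,6}: U = 0; exhaustive two-sided p = 2 * 1/choose(6,3)
  mw <- compare_groups(1:3, 4:6, "mannwhitney")
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p, 0.1, tolerance = 1e-12)
  # identical samples are not distinguishable
  x <- c(1.3, 2.1, 0.7, 1.9)
  expect_gte(compare_groups(x, x, "mannwhitney")$p, 0.99)
  # clear shift detected by both tests
  set.seed(8)
  a <- rnorm(50)
  b <- rnorm(50, 3)
  expect_lt(compare_groups(a, b, "mannwhitney")$p, 1e-3)
  expect_lt(compare_groups(a, b, "welch")$p, 1e-3)
  # auto: normal data -> Welch, skewed -> Mann-Whitney
  expect_equal(compare_groups(a, b, "auto")$test, "welch")
  expect_equal(compare_groups(exp(a), exp(b), "auto")$test, "mannwhitney")
  expect_warning(tied <- compare_groups(rep(1, 5), rep(1, 5)), "tied")
  expect_equal(tied$p, 1)
})

test_that("bootstrap median CI: degenerate and coverage behaviour", {
  expect_equal(bootstrap_median_ci(rep(2.5, 10), seed = 1), c(2.5, 2.5))
  one <- bootstrap_median_ci(c(1, 2, 3, 4, 100), n_boot = 1, seed = 2)
  expect_equal(one[1], one[2])
  set.seed(9)
  x <- rnorm(1000)
  hits <- vapply(1:20, function(s) {
    ci <- bootstrap_median_ci(x, n_boot = 400, seed = s)
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # determinism
  expect_identical(bootstrap_median_ci(x, seed = 3),
                   bootstrap_median_ci(x, seed = 3))
})

test_that("leave-one-feature-out attribution finds planted signal", {
  tab <- two_class_table(n_per_class = 40, p = 7, informative = 1,
                         effect = 1.5, well_cv = 0.08, seed = 16)
  at <- loocv_attribution(tab, "control", "mutant", "SVM",
                          fast_cv(seed = 16, n_repeats = 3), fast_grid)
  expect_equal(at$table$feature[1], "f01")
  expect_gt(at$table$dz[1], max(at$table$dz[-1]) + 0.1)
  expect_equal(nrow(at$table), 7)
  expect_error(loocv_attribution(tab[c(names(tab)[1:7], "f01")],
                                 "control", "mutant"), "leave one out")
})

test_that("duplicated informative features null each other's attribution", {
  tab <- two_class_table(n_per_class = 40, p = 6, informative = 1,
                         effect = 1.5, well_cv = 0.08, seed = 17)
  tab$f_dup <- tab$f01 * (1 + rnorm(nrow(tab), 0, 1e-4))
  class(tab) <- c("feature_table", "data.frame")
  at <- loocv_attribution(tab, "control", "mutant", "SVM",
                          fast_cv(seed = 17, n_repeats = 3), fast_grid)
  dz <- setNames(at$table$dz, at$table$feature)
  expect_lt(abs(dz[["f01"]]), 0.05)
  expect_lt(abs(dz[["f_dup"]]), 0.05)
})
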