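test_that("heterogeneity statistics match hand arithmetic", {
  expect_equal(cochran_q(rep(0.3, 3), c(0.1, 0.2, 0.3)), 0)
  expect_equal(cochran_q(c(0, 1), c(0.1, 0.1)), 5.0, tolerance = 1e-12)
  expect_equal(cochran_q(0.4, 0.2), 0)
  expect_equal(dl_tau2(c(0, 1), c(0.1, 0.1)), 0.4, tolerance = 1e-12)
  expect_equal(dl_tau2(rep(0.5, 4), c(0.1, 0.2, 0.1, 0.3)), 0)
  expect_equal(dl_tau2(0.4, 0.2), 0)
  expect_equal(i_squared(5, 2), 80.0)
  expect_equal(i_squared(0.5, 3), 0)  # Q < k-1 truncates
  expect_equal(i_squared(0, 5), 0)
})

test_that("random-effects pooling honors its closed forms", {
  # single estimate: pooled = d, SE = sqrt(v)
  p1 <- pool_random_effects(0.3, 0.04, tau2 = 0)
  expect_equal(p1$d_pooled, 0.3)
  expect_equal(p1$se, 0.2)
  # k identical estimates at tau2 = 0: SE = sqrt(v/k)
  pk <- pool_random_effects(rep(0.3, 4), rep(0.04, 4), tau2 = 0)
  expect_equal(pk$d_pooled, 0.3)
  expect_equal(pk$se, sqrt(0.04 / 4), tolerance = 1e-12)
  # Wald CI uses the 1.959964 normal critical value
  ci <- wald_ci(-0.29, 0.18)
  expect_equal(unname(ci["lb"]), -0.29 - qnorm(0.975) * 0.18)
  expect_equal(qnorm(0.975), 1.959964, tolerance = 1e-6)
})

test_that("DL pipeline matches the straight-line oracle on random instances", {
  set.seed(42)
  for (rep in 1:200) {
    k <- sample(2:10, 1)
    inst <- random_instance(k)
    ours <- pool_random_effects(inst$d, inst$v, dl_tau2(inst$d, inst$v))
    orc <- oracle_meta(inst$d, inst$v)
    expect_equal(ours$d_pooled, orc$d, tolerance = 1e-12)
    expect_equal(ours$se, orc$se, tolerance = 1e-12)
    expect_equal(ours$p, orc$p, tolerance = 1e-12)
    expect_equal(ours$tau2, orc$tau2, tolerance = 1e-12)
    expect_equal(ours$I2, orc$I2, tolerance = 1e-12)
  }
})

test_that("REML tau2 matches grid search, metafor, and its boundary cases", {
  expect_equal(reml_tau2(rep(0.4, 3), rep(0.1, 3)), 0)
  expect_equal(reml_tau2(c(0.2, 0.2), c(0.05, 0.05)), 0)
  inst <- list(d = c(0, 1), v = c(0.1, 0.1))
  expect_equal(reml_tau2(inst$d, inst$v),
               oracle_reml_grid(inst$d, inst$v), tolerance = 1e-3)
  set.seed(17)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    inst <- random_instance(k)
    t_ours <- reml_tau2(inst$d, inst$v)
    expect_equal(t_ours, oracle_reml_grid(inst$d, inst$v, upper = 5),
                 tolerance = 1e-3)
    t_metafor <- metafor::rma(yi = inst$d, vi = inst$v,
                              method = "REML")$tau2
    expect_equal(t_ours, t_metafor, tolerance = 1e-4)
  }
  expect_error(reml_tau2(c(0, 0.5, 1.2), c(0.05, 0.2, 0.1), max_iter = 1L,
                         tol = 1e-14), "converge")
  expect_error(reml_tau2(0.3, 0.1), "at least 2")
})

test_that("DL pooled results agree with metafor on site-shaped instances", {
  set.seed(23)
  for (rep in 1:10) {
    inst <- random_instance(7)
    fit <- metafor::rma(yi = inst$d, vi = inst$v, method = "DL")
    ours <- pool_random_effects(inst$d, inst$v, dl_tau2(inst$d, inst$v))
    expect_equal(ours$d_pooled, as.numeric(fit$b), tolerance = 1e-10)
    expect_equal(ours$se, fit$se, tolerance = 1e-10)
    expect_equal(ours$ci_lb, fit$ci.lb, tolerance = 1e-10)
    expect_equal(ours$tau2, fit$tau2, tolerance = 1e-10)
  }
})

test_that("meta_analyze aggregates per outcome and enforces symmetric outcome sets", {
  tabs <- generate_consortium(profiles = default_profiles()[1:3, ],
                              effects = effect_spec(), seed = 5)
  locals <- lapply(tabs, local_compute)
  fit <- meta_analyze(locals)
  expect_s3_class(fit, "meta_result")
  expect_identical(fit$pooled$outcome, outcome_names())
  # per-outcome equality with the straight-line oracle
  for (oc in outcome_names()) {
    rows <- fit$sites[fit$sites$outcome == oc, ]
    orc <- oracle_meta(rows$d, rows$v)
    i <- which(fit$pooled$outcome == oc)
    expect_equal(fit$pooled$d[i], orc$d, tolerance = 1e-12)
    expect_equal(fit$pooled$se[i], orc$se, tolerance = 1e-12)
    expect_equal(fit$pooled$Q[i], orc$Q, tolerance = 1e-12)
    # pooled d is a convex combination of site d's
    expect_gte(fit$pooled$d[i], min(rows$d) - 1e-12)
    expect_lte(fit$pooled$d[i], max(rows$d) + 1e-12)
  }
  expect_named(coef(fit), outcome_names())
  # one site: pooled equals the site effect
  fit1 <- meta_analyze(locals[1])
  expect_equal(fit1$pooled$d, locals[[1]]$effects$d)
  expect_equal(fit1$pooled$se, sqrt(locals[[1]]$effects$v))
  # asymmetric outcome sets abort with the offender named
  broken <- locals
  broken[[2]]$effects <- broken[[2]]$effects[-3, ]
  expect_error(meta_analyze(broken), "EXP")
})

test_that("DL and REML coincide on exactly homogeneous inputs", {
  d <- rep(-0.3, 5); v <- rep(0.08, 5)
  loc <- lapply(1:5, function(i) structure(
    list(site_id = paste0("s", i),
         effects = data.frame(outcome = outcome_names(), d = d[i], v = v[i],
                              n_M = 20L, n_F = 10L,
                              stringsAsFactors = FALSE),
         warnings = character()), class = "local_result"))
  f_dl <- meta_analyze(loc, estimator = "DL")
  f_reml <- meta_analyze(loc, estimator = "REML")
  expect_equal(f_dl$pooled$tau2, rep(0, 8))
  expect_equal(f_reml$pooled$tau2, rep(0, 8))
  expect_equal(f_dl$pooled$d, f_reml$pooled$d)
  expect_equal(f_dl$pooled$se, f_reml$pooled$se)
})

test_that("adding a site at tau2 = 0 strictly decreases the pooled SE", {
  d <- c(0.1, 0.2, 0.15); v <- c(0.05, 0.07, 0.06)
  se3 <- pool_random_effects(d, v, 0)$se
  se4 <- pool_random_effects(c(d, 0.5), c(v, 0.5), 0)$se
  expect_lt(se4, se3)
})

test_that("outlier flagging responds only to genuine deviants", {
  tabs <- generate_consortium(profiles = default_profiles()[1:4, ],
                              effects = effect_spec(), seed = 9)
  fit <- meta_analyze(lapply(tabs, local_compute))
  flags <- flag_outlier_sites(fit, threshold = 3)
  expect_false(any(flags$flagged))       # homogeneous truth: no flags
  expect_false(any(flag_outlier_sites(fit, threshold = Inf)$flagged))
  # plant a deviant site 10 standardized units out
  i <- which(fit$pooled$outcome == "Total")
  dev <- fit$sites
  j <- which(dev$outcome == "Total")[1]
  dev$d[j] <- fit$pooled$d[i] + 10 * sqrt(dev$v[j] + fit$pooled$tau2[i])
  fit2 <- fit; fit2$sites <- dev
  expect_true(flag_outlier_sites(fit2)$flagged[
    flag_outlier_sites(fit2)$outcome == "Total" &
      flag_outlier_sites(fit2)$site_id == dev$site_id[j]][1])
})

test_that("forest rows normalize weights and mirror the pooled summary", {
  tabs <- generate_consortium(profiles = default_profiles()[1:5, ],
                              effects = effect_spec(), seed = 10)
  fit <- meta_analyze(lapply(tabs, local_compute))
  ft <- forest_rows(fit, "EXP")
  expect_equal(sum(ft$rows$weight), 100, tolerance = 1e-9)
  i <- which(fit$pooled$outcome == "EXP")
  expect_equal(ft$summary$d, fit$pooled$d[i])
  expect_equal(ft$summary$ci_lb, fit$pooled$ci_lb[i])
  # equal-v sites at tau2 = 0 get equal weights
  loc <- lapply(1:3, function(i) structure(
    list(site_id = paste0("s", i),
         effects = data.frame(outcome = outcome_names(), d = 0.2, v = 0.1,
                              n_M = 15L, n_F = 8L, stringsAsFactors = FALSE),
         warnings = character()), class = "local_result"))
  ft_eq <- forest_rows(meta_analyze(loc), "Total")
  expect_equal(ft_eq$rows$weight, rep(100 / 3, 3), tolerance = 1e-9)
  # single site: weight 100, summary equals the row
  ft1 <- forest_rows(meta_analyze(loc[1]), "Total")
  expect_equal(ft1$rows$weight, 100)
  expect_equal(ft1$summary$d, ft1$rows$d)
  expect_error(forest_rows(fit, "Nope"), "unknown outcome")
})
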