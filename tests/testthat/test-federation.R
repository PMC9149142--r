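test_that("single-shot federation equals the centralized fit exactly", {
  set.seed(61)
  for (rep in 1:5) {
    k <- sample(2:5, 1)
    profs <- default_profiles()[sample(7, k), ]
    tabs <- generate_consortium(profs, effect_spec(tau = 0.1),
                                seed = 100 + rep)
    run <- suppressWarnings(run_single_shot(spec_for(tabs), tabs))
    central <- meta_analyze(lapply(tabs, local_compute))
    for (col in c("d", "se", "z", "p", "ci_lb", "ci_ub", "tau2", "Q", "I2")) {
      expect_equal(run$result$pooled[[col]], central$pooled[[col]],
                   tolerance = 1e-12)
    }
  }
})

test_that("a one-member consortium pools to its own site effect", {
  tabs <- generate_consortium(default_profiles()[1, ], effect_spec(),
                              seed = 3)
  run <- run_single_shot(spec_for(tabs), tabs)
  local <- local_compute(tabs[[1]])
  expect_equal(run$result$pooled$d, local$effects$d)
  expect_equal(run$result$pooled$se, sqrt(local$effects$v))
})

test_that("a member without a mapped table aborts before any message", {
  tabs <- generate_consortium(default_profiles()[1:2, ], effect_spec(),
                              seed = 4)
  spec <- consortium_spec("broken", members = c(names(tabs), "ghost"))
  expect_error(run_single_shot(spec, tabs), "ghost")
})

test_that("the privacy guard admits summary payloads and rejects leaks", {
  tabs <- generate_consortium(default_profiles()[1, ], effect_spec(),
                              seed = 6)
  payload <- local_compute(tabs[[1]])$effects
  expect_invisible(privacy_guard(payload, site_n = nrow(tabs[[1]])))
  # smuggled per-subject vector: extra column
  leak1 <- payload
  leak1$scores <- list(rnorm(nrow(tabs[[1]])))
  expect_error(privacy_guard(leak1, nrow(tabs[[1]])),
               class = "privacy_violation")
  # smuggled attribute
  leak2 <- payload
  attr(leak2, "raw") <- rnorm(nrow(tabs[[1]]))
  expect_error(privacy_guard(leak2, nrow(tabs[[1]])),
               class = "privacy_violation")
  # payload that is the record-level table itself
  expect_error(privacy_guard(as.data.frame(tabs[[1]]), nrow(tabs[[1]])),
               class = "privacy_violation")
  # min_cell: a single-subject cell passes at the default with a warning
  small <- payload
  small$n_F <- 1L
  expect_warning(privacy_guard(small, nrow(tabs[[1]]), min_cell = 1),
                 "small-cell")
  expect_error(suppressWarnings(privacy_guard(small, nrow(tabs[[1]]),
                                              min_cell = 2)),
               class = "privacy_violation")
})

test_that("message bytes are invariant to a site's record count", {
  prof <- default_profiles()[1, ]
  prof2 <- prof
  prof2$n_M <- prof$n_M * 2L
  prof2$n_F <- prof$n_F * 2L
  t1 <- generate_consortium(prof, effect_spec(), seed = 8)
  t2 <- generate_consortium(prof2, effect_spec(), seed = 8)
  b1 <- run_single_shot(spec_for(t1), t1)$log$messages[[1]]$bytes
  b2 <- run_single_shot(spec_for(t2), t2)$log$messages[[1]]$bytes
  expect_identical(b1, b2)
})

test_that("isolation: no site context ever reads a foreign table", {
  tabs <- generate_consortium(default_profiles()[1:4, ], effect_spec(),
                              seed = 9)
  run <- suppressWarnings(run_single_shot(spec_for(tabs), tabs))
  log <- run$log$access_log
  expect_identical(nrow(log), 4L)
  expect_true(all(log$requester == log$table))
})

test_that("replaying the run log reproduces the result bit-for-bit", {
  tabs <- generate_consortium(default_profiles()[1:3, ], effect_spec(),
                              seed = 11)
  run <- suppressWarnings(run_single_shot(spec_for(tabs), tabs))
  expect_identical(replay_run(run$log), run$result)
  # and the serialized audit log round-trips numerically
  path <- file.path(tempdir(), "runlog.jsonl")
  write_run_log(run$log, path)
  lines <- readLines(path)
  expect_identical(length(lines), 3L)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$payload$d,
               run$log$messages[[1]]$payload$d, tolerance = 1e-14)
})

test_that("Laplace noising is seeded, mean-zero, and vanishes at huge epsilon", {
  tabs <- generate_consortium(default_profiles()[1, ], effect_spec(),
                              seed = 13)
  local <- local_compute(tabs[[1]])
  near <- apply_dp_noise(local, epsilon = 1e9, sensitivity = c(d = 1),
                         seed = 1)
  expect_equal(near$effects$d, local$effects$d, tolerance = 1e-6)
  n1 <- apply_dp_noise(local, 1, c(d = 1), seed = 42)
  n2 <- apply_dp_noise(local, 1, c(d = 1), seed = 42)
  expect_identical(n1$effects$d, n2$effects$d)
  expect_false(identical(n1$effects$d, local$effects$d))
  # counts are never designated
  expect_error(apply_dp_noise(local, 1, c(n_F = 1)), "never noised")
  expect_error(apply_dp_noise(local, -1, c(d = 1)), "epsilon")
  # MC: mean of the noised d is the true d within 3 MC standard errors
  eps <- 0.5
  reps <- vapply(1:10000, function(i) {
    apply_dp_noise(local, eps, c(d = 1), seed = i)$effects$d[3]
  }, numeric(1))
  scale <- 1 / eps
  se_mc <- sqrt(2 * scale^2 / 10000)
  expect_lt(abs(mean(reps) - local$effects$d[3]), 3 * se_mc)
})

test_that("noising leaves the caller's RNG state untouched", {
  tabs <- generate_consortium(default_profiles()[1, ], effect_spec(),
                              seed = 14)
  local <- local_compute(tabs[[1]])
  set.seed(1234)
  before <- .Random.seed
  invisible(apply_dp_noise(local, 1, c(d = 1), seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("sufficient-statistics regression equals pooled least squares", {
  tabs <- generate_consortium(default_profiles()[1:2, ],
                              effect_spec(tau = 0.2), seed = 15)
  spec <- spec_for(tabs)
  # centralized oracle: lm on the concatenated scored data
  scores <- do.call(rbind, lapply(tabs, function(t) {
    s <- score_table(t)
    s$age <- t$age[match(s$subject_id, t$subject_id)]
    s
  }))
  fit_c <- lm(Total ~ I(gender == "F"), data = scores)
  fed <- run_iterative_regression(spec, tabs, outcome = "Total",
                                  mode = "sufficient_stats")
  expect_equal(unname(fed$coefficients),
               unname(coef(fit_c)), tolerance = 1e-10)
  expect_equal(fed$sigma, summary(fit_c)$sigma, tolerance = 1e-10)
  # single site reduces to that site's own least squares
  one <- run_iterative_regression(spec_for(tabs[1]), tabs[1],
                                  outcome = "Total",
                                  mode = "sufficient_stats")
  s1 <- score_table(tabs[[1]])
  expect_equal(unname(one$coefficients),
               unname(coef(lm(Total ~ I(gender == "F"), data = s1))),
               tolerance = 1e-10)
  # with standardized age the fit still matches the centralized one
  fed_age <- run_iterative_regression(spec, tabs, outcome = "EXP",
                                      predictors = c("gender", "age"),
                                      mode = "sufficient_stats")
  scores$age_std <- (scores$age - mean(scores$age)) / sd(scores$age)
  fit_age <- lm(EXP ~ I(gender == "F") + age_std, data = scores)
  expect_equal(unname(fed_age$coefficients), unname(coef(fit_age)),
               tolerance = 1e-10)
})

test_that("gradient rounds converge to the sufficient-statistics solution", {
  tabs <- generate_consortium(default_profiles()[c(1, 3), ],
                              effect_spec(), seed = 16)
  spec <- spec_for(tabs)
  exact <- run_iterative_regression(spec, tabs, outcome = "MAP",
                                    mode = "sufficient_stats")
  grad <- run_iterative_regression(spec, tabs, outcome = "MAP",
                                   mode = "gradient", tol = 1e-10)
  expect_equal(unname(grad$coefficients), unname(exact$coefficients),
               tolerance = 1e-6)
  expect_gt(grad$rounds, 1L)
  expect_error(run_iterative_regression(spec, tabs, outcome = "MAP",
                                        mode = "gradient", tol = 1e-12,
                                        max_rounds = 3L), "converge")
})

test_that("a singular pooled design raises a rank error", {
  tabs <- generate_consortium(default_profiles()[1, ], effect_spec(),
                              seed = 17)
  only_m <- as.data.frame(tabs[[1]])
  only_m <- only_m[only_m$gender == "M", ]
  # keep both genders out: constant indicator makes the design singular
  tab_m <- canonical_table(only_m, "test1")
  expect_error(run_iterative_regression(spec_for(list(test1 = tab_m)),
                                        list(test1 = tab_m),
                                        outcome = "Total",
                                        mode = "sufficient_stats"),
               "singular|degenerate")
})
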