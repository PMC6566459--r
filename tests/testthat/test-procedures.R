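test_that("with a single hypothesis every procedure reduces to the plain test", {
  des1 <- nested_design(1, alpha = 0.025)
  for (s in 1:6) {
    d <- simulate_trial(model_spec(beta1 = 0.4, n_per_group = 40), seed = 100 + s)
    ref <- run_procedure("full_population", d, des1)
    for (pr in c("sidak", "t_gs", "adjusted_t", "inverse_normal")) {
      r <- run_procedure(pr, d, des1)
      expect_equal(r$table$reject, ref$table$reject,
                   info = paste(pr, "seed", s))
    }
    # the z-variant compares the t statistic to the normal quantile
    rz <- run_procedure("z_gs", d, des1)
    expect_equal(rz$table$boundary, qnorm(0.975), tolerance = 1e-6)
  }
})

test_that("an overwhelming uniform effect is rejected everywhere by everyone", {
  d <- simulate_trial(model_spec(beta1 = 10, n_per_group = 80), seed = 7)
  des <- quartile_design()
  for (pr in c("sidak", "z_gs", "t_gs", "adjusted_t", "regression",
               "inverse_normal")) {
    r <- run_procedure(pr, d, des, mode = "simulation")
    expect_true(all(r$table$reject), info = pr)
  }
})

test_that("Sidak boundaries dominate correlation-aware boundaries", {
  # Sidak ignores the positive correlation of nested statistics, so its
  # t-scale critical values are larger
  d <- simulate_trial(null_step_spec(n = 80), seed = 19)
  des <- quartile_design()
  b_sidak <- run_procedure("sidak", d, des)$table$boundary
  b_adj <- run_procedure("adjusted_t", d, des)$table$boundary
  expect_true(all(b_sidak >= b_adj))
})

test_that("adjusted p-values are coherent with rejections across levels", {
  des <- nested_design(c(0.4, 0.7, 1), alpha = 0.025)
  for (s in 1:3) {
    d <- simulate_trial(alt_step_spec(effect = 0.6, n = 60), seed = 200 + s)
    for (pr in c("sidak", "adjusted_t", "inverse_normal")) {
      adjp <- adjusted_pvalues(pr, d, des)
      for (a in c(0.025, 0.1, 0.3)) {
        rej <- run_procedure(pr, d, des, alpha = a)$table$reject
        clear <- abs(adjp - a) > 1e-6
        expect_equal(rej[clear], (adjp <= a)[clear],
                     info = paste(pr, "alpha", a, "seed", s))
      }
    }
  }
})

test_that("Sidak adjusted p-values match the closed form", {
  d <- simulate_trial(alt_step_spec(effect = 0.8, n = 50), seed = 31)
  des <- quartile_design()
  adjp <- adjusted_pvalues("sidak", d, des)
  st <- t_statistic(summarize_subgroups(d, des))
  praw <- pt(st$values, st$df, lower.tail = FALSE)
  expect_lt(max(abs(adjp - (1 - (1 - praw)^4))), 1e-6)
})

test_that("K = 1 adjusted p-value equals the raw one-sided p-value", {
  d <- simulate_trial(model_spec(beta1 = 0.5, n_per_group = 40), seed = 41)
  des1 <- nested_design(1)
  st <- t_statistic(summarize_subgroups(d, des1))
  praw <- pt(st$values, st$df, lower.tail = FALSE)
  expect_lt(abs(adjusted_pvalues("adjusted_t", d, des1) - praw), 1e-7)
  expect_lt(abs(adjusted_pvalues("sidak", d, des1) - praw), 1e-7)
})

test_that("larger statistics give smaller adjusted p-values", {
  d <- simulate_trial(alt_step_spec(effect = 0.3, n = 50), seed = 53)
  des <- nested_design(c(0.5, 1))
  shifted <- d; shifted$y <- d$y + 0.4 * d$u   # constant uplift, variances fixed
  for (pr in c("sidak", "adjusted_t")) {
    p0 <- adjusted_pvalues(pr, d, des)
    p1 <- adjusted_pvalues(pr, shifted, des)
    expect_true(all(p1 < p0), info = pr)
  }
})

test_that("decisions are shift-invariant and scale-equivariant", {
  d <- simulate_trial(alt_step_spec(effect = 0.7, n = 60), seed = 61)
  des <- quartile_design()
  shifted <- d; shifted$y <- d$y + 100
  scaled <- d; scaled$y <- d$y * 7
  for (pr in c("sidak", "t_gs", "adjusted_t", "regression", "inverse_normal")) {
    r0 <- run_procedure(pr, d, des, mode = "simulation")$table$reject
    expect_equal(run_procedure(pr, shifted, des,
                               mode = "simulation")$table$reject, r0,
                 info = paste(pr, "shift"))
    expect_equal(run_procedure(pr, scaled, des,
                               mode = "simulation")$table$reject, r0,
                 info = paste(pr, "scale"))
  }
})

test_that("rejections persist on sub-families of hypotheses (closure coherence)", {
  # a hypothesis rejected within the full family is also rejected when the
  # procedure is run on any threshold subset containing it: the basis for
  # strong FWER control via closed testing
  des_full <- quartile_design()
  subsets <- list(c(1), c(2), c(1, 2), c(2, 3), c(1, 3, 4), c(2, 4),
                  c(1, 2, 3, 4))
  for (s in 1:5) {
    d <- simulate_trial(alt_step_spec(effect = 0.6, n = 60), seed = 300 + s)
    for (pr in c("sidak", "t_gs", "adjusted_t")) {
      rej_full <- run_procedure(pr, d, des_full, mode = "simulation")$table$reject
      for (sub in subsets) {
        des_sub <- nested_design(des_full$thresholds[sub], alpha = 0.025)
        rej_sub <- run_procedure(pr, d, des_sub, mode = "simulation")$table$reject
        expect_true(all(rej_sub[rej_full[sub]]),
                    info = paste(pr, "seed", s, "subset",
                                 paste(sub, collapse = "")))
      }
    }
  }
})

test_that("STEPP tail-oriented subgroups form the 2K-1 sets", {
  g1 <- stepp_tail_subgroups(1)
  expect_equal(g1$K, 1)
  g3 <- stepp_tail_subgroups(c(0.25, 0.5, Inf))
  expect_equal(g3$K, 5)
  x <- runif(50)
  masks <- subgroup_membership(x, g3)
  # the full population appears once
  expect_true(all(masks[, 3]))
  # left and right sets at the same threshold partition the population
  expect_equal(masks[, 1] + masks[, 4], rep(1, 50))
  expect_equal(masks[, 2] + masks[, 5], rep(1, 50))
})

test_that("general-subgroup testing agrees with the nested procedure on nested sets", {
  d <- simulate_trial(alt_step_spec(effect = 0.8, n = 60), seed = 71)
  thr <- c(0.3, 0.6, 1)
  gs <- general_subgroups(lapply(thr, function(q) c(-Inf, q)))
  rg <- run_general_procedure(d, gs, alpha = 0.025)
  rn <- run_procedure("adjusted_t", d, nested_design(thr),
                      covariance_form = "general")
  expect_equal(rg$table$statistic, rn$table$statistic)
  expect_equal(rg$table$boundary, rn$table$boundary, tolerance = 1e-5)
  expect_equal(rg$table$reject, rn$table$reject)
})

test_that("disjoint subgroups get the independence critical value", {
  d <- simulate_trial(null_step_spec(delta = 0, n = 80), seed = 83)
  gs <- general_subgroups(list(c(-Inf, 0.5), c(0.5, Inf)))
  r <- run_general_procedure(d, gs, alpha = 0.025)
  # 1 - Phi(c)^2 = alpha  =>  c = Phi^{-1}(sqrt(1 - alpha))
  expect_equal(r$table$c_normal, rep(qnorm(sqrt(0.975)), 2), tolerance = 1e-5)
})

test_that("single general subgroup reduces to the plain t-test", {
  d <- simulate_trial(model_spec(beta1 = 0.5, n_per_group = 40), seed = 89)
  r <- run_general_procedure(d, general_subgroups(list(c(-Inf, Inf))),
                             alpha = 0.025)
  tt <- t.test(d$y[d$u == 1], d$y[d$u == 0], var.equal = TRUE,
               alternative = "greater")
  expect_equal(r$table$statistic, unname(tt$statistic))
  expect_equal(r$table$c_normal, qnorm(0.975), tolerance = 1e-6)
})

test_that("user-supplied general critical values are validated", {
  d <- simulate_trial(null_step_spec(delta = 0, n = 80), seed = 97)
  gs <- general_subgroups(list(c(-Inf, 0.5), c(-Inf, Inf)))
  # Bonferroni values are conservative, hence accepted
  ok <- run_general_procedure(d, gs, alpha = 0.025,
                              critical_values = rep(qnorm(1 - 0.0125), 2))
  expect_lte(ok$attained_alpha, 0.025 + 1e-6)
  # unadjusted values exceed the level and are refused
  expect_error(run_general_procedure(d, gs, alpha = 0.025,
                                     critical_values = rep(qnorm(0.975), 2)),
               "attain")
})

test_that("degenerate subgroups error in analysis mode, count in simulation mode", {
  d <- simulate_trial(model_spec(n_per_group = 40), seed = 101)
  des <- nested_design(c(0.002, 1))   # first subgroup (almost surely) empty
  expect_error(run_procedure("adjusted_t", d, des), "merge")
  r <- run_procedure("adjusted_t", d, des, mode = "simulation")
  expect_false(r$table$reject[1])
  expect_gte(r$n_degenerate, 1)
})
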