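test_that("BH adjustment matches the step-up formula oracle", {
  expect_equal(bh_adjust(0.37), 0.37)                 # single p unchanged
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               oracle_bh(c(0.01, 0.02, 0.03, 0.04)))
  set.seed(31)
  for (rep in 1:200) {
    p <- runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    # invariant under permutation of input order
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm])[order(perm)], adj)
    # monotone non-decreasing in p-value rank, capped at 1
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})

test_that("Mann-Whitney U matches exact enumeration for small samples", {
  x <- c(1.2, 3.4, 5.1, 7.9)
  y <- c(2.2, 4.7, 6.3, 8.8)
  res <- mann_whitney(x, y)
  expect_equal(res$method, "exact")
  expect_equal(res$p, oracle_mw_exact(x, y), tolerance = 1e-12)
  set.seed(17)
  for (rep in 1:30) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    v <- sample(seq(0.1, 50, by = 0.1), n1 + n2)  # distinct values
    xx <- v[1:n1]; yy <- v[-(1:n1)]
    expect_equal(mann_whitney(xx, yy)$p, oracle_mw_exact(xx, yy),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U obeys its structural identities", {
  x <- c(3, 1, 4, 1, 5)
  y <- c(9, 2, 6, 5)
  expect_equal(mann_whitney(x, x)$U, length(x)^2 / 2)  # identical multisets
  expect_equal(mann_whitney(x, y)$U + mann_whitney(y, x)$U,
               length(x) * length(y))
  # complete separation pins U at an extreme
  expect_equal(mann_whitney(1:4, 11:14)$U, 0)
  expect_equal(mann_whitney(11:14, 1:4)$U, 16)
  # large/tied samples use the tie-corrected normal approximation
  set.seed(4)
  big <- mann_whitney(rpois(30, 3), rpois(25, 4))
  expect_equal(big$method, "normal_tie_corrected")
  expect_true(big$p > 0 && big$p <= 1)
})

test_that("partial Pearson correlation residualises correctly", {
  set.seed(23)
  x <- rnorm(40)
  y <- 0.5 * x + rnorm(40)
  # no covariates reduces to the plain Pearson correlation and its t test
  plain <- partial_pearson(x, y)
  ct <- stats::cor.test(x, y)
  expect_equal(plain$r, unname(ct$estimate))
  expect_equal(plain$p, ct$p.value, tolerance = 1e-12)
  # y = x gives r = 1 for covariates not collinear with x
  z <- rnorm(40)
  expect_equal(partial_pearson(x, x, data.frame(z))$r, 1)
  # random data matches the precision-matrix oracle
  for (rep in 1:50) {
    n <- sample(10:40, 1)
    Z <- matrix(rnorm(n * 2), ncol = 2)
    xx <- rnorm(n) + Z %*% c(1, -0.5)
    yy <- rnorm(n) + Z %*% c(-0.3, 0.8)
    res <- partial_pearson(xx, yy, as.data.frame(Z))
    expect_equal(res$r, oracle_partial_r(xx, yy, Z), tolerance = 1e-10)
    expect_equal(res$df, n - 4L)
  }
  expect_warning(out <- partial_pearson(x, rep(1, 40)), "degenerate")
  expect_true(is.na(out$r))
  expect_error(partial_pearson(1:3, 1:3, data.frame(a = 1:3, b = 4:6)),
               "complete cases")
})

test_that("chi-squared on counts matches the hand formula", {
  same <- matrix(c(10, 10, 40, 40), 2)
  expect_equal(chisq_counts(same)$X2, 0)
  tab <- matrix(c(10, 20, 90, 80), 2)
  res <- chisq_counts(tab)
  orc <- oracle_chisq(tab)
  expect_equal(res$X2, orc$X2, tolerance = 1e-12)
  expect_equal(res$p, orc$p, tolerance = 1e-12)
  expect_equal(res$df, 1)                           # df for 2x2
  expect_equal(chisq_counts(matrix(1:12, 3))$df, 6) # (3-1)(4-1)
  expect_error(chisq_counts(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("the group model recovers an injected diagnosis effect", {
  delta <- 0.06
  gp <- list(HK_control = sim_params(), US_control = sim_params(),
             HK_ASD = sim_params(p_regression = 0.1 + delta),
             US_ASD = sim_params(p_regression = 0.1 + delta))
  coh <- simulate_cohort(gp, 60, level = "metrics", seed = 91)
  cs <- aggregate_conditions(coh$run_metrics)
  fit <- fit_group_model(cs, "refixations", "symbolic")
  est <- fit$estimates
  expect_equal(est$term, c("culture", "diagnosis", "interaction"))
  # coding: diagnosis = control - ASD, so an ASD excess is negative
  d <- est[est$term == "diagnosis", ]
  truth <- -29 * delta
  expect_lt(d$estimate, 0)
  expect_lt(abs(d$estimate - truth), 2.5 * d$se)
  expect_true(all(est$se > 0))
  expect_true(all(est$p > 0 & est$p <= 1))
})

test_that("repeated rows per participant engage the mixed-model path", {
  gp <- list(HK_control = sim_params(), HK_ASD = sim_params(),
             US_control = sim_params(), US_ASD = sim_params())
  coh <- simulate_cohort(gp, 12, level = "metrics", seed = 92)
  # run-level rows: 8 per participant -> random intercept model
  fit <- fit_group_model(dplyr::filter(coh$run_metrics,
                                       condition == "symbolic"),
                         "refixations")
  expect_s4_class(fit$model, "lmerModLmerTest")
  expect_true(all(is.finite(fit$estimates$df)))
  expect_true(all(fit$estimates$df < 96))  # Satterthwaite df, not N - p
  expect_named(fit$interaction_lrt, c("chisq", "df", "p"))
  # condition summaries: one row per participant -> OLS path
  cs <- aggregate_conditions(coh$run_metrics)
  fit2 <- fit_group_model(cs, "refixations", "symbolic")
  expect_s3_class(fit2$model, "lm")
})

test_that("constant responses give zero effect estimates", {
  gp <- list(HK_control = sim_params(), HK_ASD = sim_params(),
             US_control = sim_params(), US_ASD = sim_params())
  coh <- simulate_cohort(gp, 8, level = "metrics", seed = 93)
  cs <- aggregate_conditions(coh$run_metrics)
  cs$flat <- 7
  # a perfectly constant response makes lm warn about a perfect fit
  fit <- suppressWarnings(fit_group_model(cs, "flat", "symbolic"))
  expect_equal(fit$estimates$estimate, rep(0, 3), tolerance = 1e-10)
})

test_that("IQ enters as a covariate for naming performance only", {
  gp <- list(HK_control = sim_params(), HK_ASD = sim_params(),
             US_control = sim_params(), US_ASD = sim_params())
  coh <- simulate_cohort(gp, 10, level = "metrics", seed = 94)
  cs <- aggregate_conditions(coh$run_metrics)
  fit_nt <- fit_group_model(cs, "naming_time_s", "symbolic")
  fit_rf <- fit_group_model(cs, "refixations", "symbolic")
  expect_true("iq" %in% names(coef(fit_nt$model)))
  expect_false("iq" %in% names(coef(fit_rf$model)))
})

test_that("rank-deficient designs fail loudly with the aliased term", {
  gp <- list(HK_control = sim_params(), US_ASD = sim_params())
  coh <- simulate_cohort(gp, 10, level = "metrics", seed = 95)
  cs <- aggregate_conditions(coh$run_metrics)
  # only two of four cells exist: the interaction is aliased
  expect_error(fit_group_model(cs, "refixations", "symbolic"), "aliased")
})

test_that("pairwise contrasts are Tukey-adjusted cell-mean differences", {
  gp <- list(HK_control = sim_params(), HK_ASD = sim_params(),
             US_control = sim_params(), US_ASD = sim_params())
  coh <- simulate_cohort(gp, 25, level = "metrics", seed = 96)
  cs <- aggregate_conditions(coh$run_metrics)
  fit <- fit_group_model(cs, "refixations", "symbolic")
  pc <- pairwise_contrasts(fit)
  expect_equal(nrow(pc$contrasts), 6L)  # 4 cells -> 6 pairs
  # identical generative cells: contrasts near 0, adjusted p near 1
  expect_true(all(abs(pc$contrasts$estimate) < 3 * pc$contrasts$se))
  # a large single-cell shift lands in the matching contrasts
  cs2 <- cs
  shift_rows <- cs2$culture == "HK" & cs2$diagnosis == "ASD" &
    cs2$condition == "symbolic"
  cs2$refixations[shift_rows] <- cs2$refixations[shift_rows] + 25
  pc2 <- pairwise_contrasts(fit_group_model(cs2, "refixations", "symbolic"))
  hk_asd <- grepl("ASD HK", pc2$contrasts$contrast)
  expect_true(all(pc2$contrasts$p_adj[hk_asd] < 0.001))
  expect_true(all(abs(pc2$contrasts$estimate[hk_asd]) > 15))
})

test_that("model estimates are CI-calibrated for an injected effect", {
  # parameter recovery: the injected group shift should fall inside the 95%
  # Wald CI in about 95% of replicates (checked >= 90% over 200)
  delta <- 2.0
  covered <- 0L
  set.seed(123)
  for (r in 1:200) {
    n <- 60
    tbl <- tibble::tibble(
      participant_id = sprintf("q%d", 1:(4 * n)),
      culture = rep(c("HK", "US"), each = 2 * n),
      diagnosis = rep(rep(c("ASD", "control"), each = n), 2),
      sex = sample(c("M", "F"), 4 * n, replace = TRUE),
      age = rnorm(4 * n, 19, 5),
      refixations = rnorm(4 * n, 9, 3) +
        ifelse(rep(rep(c("ASD", "control"), each = n), 2) == "ASD", delta, 0)
    )
    fit <- fit_group_model(tbl, "refixations")
    d <- fit$estimates[fit$estimates$term == "diagnosis", ]
    if (abs(d$estimate - (-delta)) <= qt(0.975, d$df) * d$se) {
      covered <- covered + 1L
    }
  }
  expect_gte(covered / 200, 0.90)
})
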