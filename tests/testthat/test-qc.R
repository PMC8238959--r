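test_that("positional exclusion retains serial indices 2..31 by default", {
  mask <- positional_exclusion_mask(36)
  expect_equal(which(mask) - 1L, 2:31)
  expect_equal(sum(mask), 30L)
  all_in <- positional_exclusion_mask(36, qc_params(exclude_first_items = 0,
                                                    exclude_last_items = 0))
  expect_true(all(all_in))
  # retained size = n - first - last for arbitrary settings
  set.seed(2)
  for (rep in 1:20) {
    f <- sample(0:5, 1); l <- sample(0:5, 1); n <- sample((f + l + 1):60, 1)
    m <- positional_exclusion_mask(n, qc_params(exclude_first_items = f,
                                                exclude_last_items = l))
    expect_equal(sum(m), n - f - l)
    if (f > 0) expect_false(any(m[1:f]))
    if (l > 0) expect_false(any(m[(n - l + 1):n]))
  }
  expect_error(positional_exclusion_mask(6), "too small")
})

test_that("track loss above 35% fails a run and exactly 35% passes", {
  geo <- test_geometry()
  tr40 <- stationary_trace(20, rate = 60)
  n <- nrow(tr40$samples)
  kill <- seq_len(round(0.4 * n))
  tr40$samples$lvalid[kill] <- FALSE
  tr40$samples$rvalid[kill] <- FALSE
  fx <- ivt_classify(tr40, geo)
  verdict <- evaluate_run_qc(tr40, fx, run_spec("p", "color"),
                             qc_params(fixation_bounds = list(
                               symbolic = c(1, 99), non_symbolic = c(1, 99))))
  expect_false(verdict$qc_pass)
  expect_true("track_loss" %in% verdict$qc_reasons)
})

test_that("fixation-count bounds depend on condition and accumulate reasons", {
  geo <- test_geometry()
  tr <- stationary_trace(2)
  fx55 <- fixation_table(start = seq_len(55) / 40, end = seq_len(55) / 40 + 0.01,
                         x = 640, y = 512)
  v <- evaluate_run_qc(tr, fx55, run_spec("p", "number"))  # symbolic: max 50
  expect_false(v$qc_pass)
  expect_true("fixation_count" %in% v$qc_reasons)
  v2 <- evaluate_run_qc(tr, fx55, run_spec("p", "color")) # non-symbolic: max 55
  expect_false("fixation_count" %in% v2$qc_reasons)
  # a run can fail several rules at once; reasons accumulate
  tr_long <- stationary_trace(30)
  half <- which(tr_long$samples$t > 2)
  tr_long$samples$lvalid[half] <- FALSE
  tr_long$samples$rvalid[half] <- FALSE
  fx <- ivt_classify(tr_long, geo)
  v3 <- evaluate_run_qc(tr_long, fx, run_spec("p", "number"))
  expect_setequal(v3$qc_reasons,
                  c("track_loss", "fixation_gap", "fixation_count"))
})

test_that("clean simulated runs pass QC with no reasons", {
  p <- sim_params(seed = 70, track_loss_frac = 0)
  sim <- simulate_run(p, test_array(), test_geometry())
  fx <- ivt_classify(sim$trace, test_geometry())
  v <- evaluate_run_qc(sim$trace, fx, sim$trace$run_spec)
  expect_true(v$qc_pass)
  expect_length(v$qc_reasons, 0)
})

test_that("condition aggregation is the stated two-stage mean", {
  base <- tibble::tibble(
    participant_id = "p1",
    stimulus_type = c("number", "number", "letter", "letter"),
    run_index = c(1, 2, 1, 2), condition = "symbolic",
    naming_time_s = c(10, 12, 11, 13),
    n_errors = 0, mean_evs_items = 1, total_fixations = 30,
    perseverations = 2, regressions = 1, refixations = 3,
    qc_pass = TRUE, qc_reasons = ""
  )
  agg <- aggregate_conditions(base)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$naming_time_s, 11.5)
  # one letter run excluded: letter mean = surviving run
  base2 <- base
  base2$qc_pass[4] <- FALSE
  agg2 <- aggregate_conditions(base2)
  expect_equal(agg2$naming_time_s, mean(c(mean(c(10, 12)), 11)))
  # two-stage mean equals the simple mean for balanced contributions
  expect_equal(agg$naming_time_s, mean(base$naming_time_s))
})

test_that("aggregation matches an independent group-by oracle on random tables", {
  set.seed(12)
  types <- c("color", "object", "number", "letter")
  rm <- tibble::tibble(
    participant_id = rep(sprintf("p%d", 1:6), each = 8),
    stimulus_type = rep(rep(types, each = 2), 6),
    run_index = rep(1:2, 24),
    condition = stimulus_condition(rep(rep(types, each = 2), 6)),
    naming_time_s = runif(48, 10, 30), n_errors = rpois(48, 1),
    mean_evs_items = runif(48, 0.5, 2), total_fixations = rpois(48, 35),
    perseverations = rpois(48, 4), regressions = rpois(48, 2),
    refixations = 0, qc_pass = runif(48) > 0.2, qc_reasons = ""
  )
  rm$refixations <- rm$perseverations + rm$regressions
  agg <- aggregate_conditions(rm)
  # oracle: nested tapply means over the passing runs only
  ok <- rm[rm$qc_pass, ]
  for (i in seq_len(nrow(agg))) {
    sub <- ok[ok$participant_id == agg$participant_id[i] &
                ok$condition == agg$condition[i], ]
    by_type <- tapply(sub$naming_time_s, sub$stimulus_type, mean)
    expect_equal(agg$naming_time_s[i], mean(by_type), tolerance = 1e-12)
  }
  # leak test: no excluded run can influence any summary
  rm2 <- rm
  rm2$naming_time_s[!rm2$qc_pass] <- 1e6
  expect_equal(aggregate_conditions(rm2), agg)
  # aggregation commutes with run reordering
  expect_equal(aggregate_conditions(rm[sample(nrow(rm)), ]), agg)
  # condition means lie within the range of contributing runs
  for (i in seq_len(nrow(agg))) {
    sub <- ok[ok$participant_id == agg$participant_id[i] &
                ok$condition == agg$condition[i], ]
    expect_gte(agg$mean_evs_items[i], min(sub$mean_evs_items))
    expect_lte(agg$mean_evs_items[i], max(sub$mean_evs_items))
  }
})

test_that("exclusion accounting tallies per-group fractions", {
  rm <- tibble::tibble(
    diagnosis = rep(c("ASD", "control"), each = 10),
    culture = "HK",
    qc_pass = c(rep(c(TRUE, FALSE), 5), rep(TRUE, 10))
  )
  acc <- exclusion_accounting(rm)
  expect_equal(acc$n_runs, c(10L, 10L))
  expect_equal(acc$frac_excluded[acc$diagnosis == "ASD"], 0.5)
  expect_equal(acc$frac_excluded[acc$diagnosis == "control"], 0)
  expect_equal(acc$n_excluded, c(5L, 0L))
  expect_equal(acc$n_included + acc$n_excluded, acc$n_runs)
})

test_that("score_run produces a coherent metrics row for a simulated run", {
  p <- sim_params(seed = 81)
  geo <- test_geometry()
  arr <- test_array("object", 2)
  sim <- simulate_run(p, arr, geo,
                      run_spec = run_spec("p9", "object", 2))
  m <- score_run(sim$trace, sim$track, arr, geo)
  expect_equal(m$refixations, m$perseverations + m$regressions)
  expect_equal(m$condition, "non_symbolic")
  expect_equal(m$qc_pass, m$qc_reasons == "")
  expect_equal(m$naming_time_s, sim$truth$naming_time)
  expect_equal(m$n_errors, sim$truth$n_errors)
})
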