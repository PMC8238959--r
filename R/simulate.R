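#' Parameters of the synthetic gaze + voice generator
#'
#' Ground-truth generative settings for one simulated RAN run. Defaults are
#' chosen to look like adolescent/adult serial naming: ~0.45 s per item plus
#' a 50 ms inter-item pause (a ~18 s run of 36 items), the eyes one item
#' ahead of the voice, a perseveration on 20% and a regression on 10% of
#' eligible items, 0.2 deg of fixation placement noise and 5% sample-level
#' track loss.
#'
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream (used when a caller manages seeding, e.g. cohort simulation).
#' @param rate_hz Gaze sampling rate (Hz).
#' @param item_duration_mean_s,item_duration_cv Mean and coefficient of
#'   variation of the lognormal per-item articulation duration.
#' @param inter_item_pause_s Silent pause between consecutive articulations.
#' @param evs_lead_items Non-negative eye lead over voice, in items; gaze
#'   occupies item `i + round(evs_lead_items)` (clamped at the last item)
#'   while item `i` is articulated.
#' @param p_perseveration Probability per eligible item of an extra
#'   same-AOI fixation (a perseveration).
#' @param p_regression Probability per eligible item of an inserted fixation
#'   on a previously visited lower-index item (a regression).
#' @param regression_depth Regression targets are drawn uniformly from
#'   previously visited retained items at most this many items back.
#' @param gaze_noise_deg SD of Gaussian angular noise added to each fixation
#'   centroid (degrees).
#' @param track_loss_frac Probability that any single sample is invalid.
#' @param error_rate Probability per item of a tagged naming error
#'   (substitution or self-correction annotation; timing unchanged).
#' @param saccade_anticipation_s How long before a vocal onset the eyes jump
#'   to that item's lead target; must exceed a few sample periods so the
#'   fixation is established by onset time.
#' @param min_segment_s Minimum scripted fixation length. Must comfortably
#'   exceed the classifier's minimum fixation duration because boundary
#'   samples adjacent to a position jump classify as saccade samples.
#' @param min_item_duration_s Lower clamp on drawn item durations.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(seed = NULL, rate_hz = 60,
                       item_duration_mean_s = 0.45, item_duration_cv = 0.25,
                       inter_item_pause_s = 0.05,
                       evs_lead_items = 1,
                       p_perseveration = 0.2, p_regression = 0.1,
                       regression_depth = 3L,
                       gaze_noise_deg = 0.2, track_loss_frac = 0.05,
                       error_rate = 0.03,
                       saccade_anticipation_s = 0.08,
                       min_segment_s = 0.18,
                       min_item_duration_s = 0.32) {
  probs <- c(p_perseveration, p_regression, track_loss_frac, error_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]",
                                       call. = FALSE)
  if (rate_hz <= 0 || item_duration_mean_s <= 0) {
    stop("rate and durations must be positive", call. = FALSE)
  }
  if (evs_lead_items < 0) stop("evs_lead_items must be non-negative", call. = FALSE)
  structure(list(seed = seed, rate_hz = rate_hz,
                 item_duration_mean_s = item_duration_mean_s,
                 item_duration_cv = item_duration_cv,
                 inter_item_pause_s = inter_item_pause_s,
                 evs_lead_items = evs_lead_items,
                 p_perseveration = p_perseveration,
                 p_regression = p_regression,
                 regression_depth = as.integer(regression_depth),
                 gaze_noise_deg = gaze_noise_deg,
                 track_loss_frac = track_loss_frac,
                 error_rate = error_rate,
                 saccade_anticipation_s = saccade_anticipation_s,
                 min_segment_s = min_segment_s,
                 min_item_duration_s = min_item_duration_s),
            class = "sim_params")
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep_len(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one RAN run with known ground truth
#'
#' The voice names the 36 items serially with lognormal articulation
#' durations. Gaze fixates item `i + round(evs_lead_items)` (clamped at 35)
#' during item i's articulation, jumping to each new target
#' `saccade_anticipation_s` before the vocal onset. On eligible items (those
#' whose gaze target lies in the retained positional range and whose window
#' fits the extra scripted fixation) a perseveration (repeat fixation within
#' the same AOI, displaced ~1 deg) or a regression (fixation on a previously
#' visited retained lower-index item within `regression_depth`) is inserted
#' with the configured probabilities, and tallied in the ground truth.
#' Fixation centroids get Gaussian angular noise; each sample is invalidated
#' independently with `track_loss_frac`. Fully reproducible from the seed.
#'
#' @param params A [sim_params()].
#' @param array A [build_array_layout()] result.
#' @param geometry A [screen_geometry()].
#' @param run_spec A [run_spec()]; defaults to a run matching the array.
#' @param retained Logical mask over serial indices defining which items
#'   count as retained for event eligibility (defaults to the standard
#'   first-2/last-4 positional exclusion).
#' @return List with `trace` (a `gaze_trace`), `track` (a `voice_track`),
#'   and `truth` (injected event counts and trial counts, per-onset true
#'   lead, true naming time, error count, and the scripted gaze segments).
#' @export
simulate_run <- function(params, array, geometry = screen_geometry(),
                         run_spec = NULL, retained = NULL) {
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(run_spec)) {
    run_spec <- run_spec("sim", array$stimulus_type, array$run_index)
  }
  if (is.null(retained)) retained <- positional_exclusion_mask(36L)
  a <- params$saccade_anticipation_s
  lead <- as.integer(round(params$evs_lead_items))
  n_items <- 36L
  px_deg <- px_per_degree(geometry)

  # voice timeline
  durations <- pmax(rlnorm_mean_cv(n_items, params$item_duration_mean_s,
                                   params$item_duration_cv),
                    params$min_item_duration_s)
  onsets <- a + c(0, cumsum(durations[-n_items] +
                              params$inter_item_pause_s))
  offsets <- onsets + durations
  err_draw <- runif(n_items) < params$error_rate
  err_tag <- ifelse(err_draw,
                    sample(c("substitution", "self_correction"), n_items,
                           replace = TRUE),
                    "")
  track <- voice_track(tibble::tibble(
    serial_index = seq_len(n_items) - 1L,
    onset_t = onsets, offset_t = offsets,
    label = array$items$label,
    error_tags = err_tag
  ), run_spec)

  # gaze script: per item window [onset - a, next onset - a)
  win_start <- onsets - a
  win_end <- c(onsets[-1] - a, offsets[n_items])
  targets <- pmin(seq_len(n_items) - 1L + lead, n_items - 1L)
  visited <- logical(n_items)
  n_pers <- 0L; n_regr <- 0L; pers_trials <- 0L; regr_trials <- 0L
  seg_item <- integer(); seg_t0 <- numeric(); seg_t1 <- numeric()
  seg_dy <- numeric()
  for (i in seq_len(n_items)) {
    tgt <- targets[i]
    window <- win_end[i] - win_start[i]
    segs <- tgt          # items fixated in this window, in order
    offs <- 0            # y displacement (deg) of each scripted fixation
    eligible <- retained[tgt + 1L]
    if (eligible && window >= 2 * params$min_segment_s) {
      pers_trials <- pers_trials + 1L
      if (runif(1) < params$p_perseveration) {
        n_pers <- n_pers + 1L
        segs <- c(segs, tgt)
        # 2.2 deg vertical within-AOI displacement. The straddling-sample
        # velocity of the repeat-fixation jump is D/(2 periods) = 30*D deg/s
        # at 60 Hz, so D must sit far above the 1.17 deg that corresponds to
        # the 35 deg/s threshold once centroid noise is added, while staying
        # inside the ~3.3 deg AOI half-height.
        offs <- c(offs, 2.2)
      }
    }
    if (eligible) {
      lo <- max(0L, tgt - params$regression_depth)
      cand <- which(visited & retained &
                      seq_len(n_items) - 1L >= lo &
                      seq_len(n_items) - 1L <= tgt - 1L) - 1L
      if (length(cand) &&
          window >= (length(segs) + 1L) * params$min_segment_s) {
        regr_trials <- regr_trials + 1L
        if (runif(1) < params$p_regression) {
          n_regr <- n_regr + 1L
          j <- if (length(cand) == 1L) cand else sample(cand, 1L)
          segs <- c(segs, j)
          offs <- c(offs, 0)
        }
      }
    }
    bounds <- win_start[i] + window * (seq_len(length(segs) + 1L) - 1L) /
      length(segs)
    seg_item <- c(seg_item, segs)
    seg_t0 <- c(seg_t0, bounds[-length(bounds)])
    seg_t1 <- c(seg_t1, bounds[-1])
    seg_dy <- c(seg_dy, offs)
    visited[segs + 1L] <- TRUE
  }

  # coalesce consecutive identical scripted fixations (the clamped lead
  # parks the eyes on the last item across several windows): they are one
  # physical fixation and must be scripted, noised, and counted as one
  same <- c(FALSE, seg_item[-1] == seg_item[-length(seg_item)] &
              seg_dy[-1] == seg_dy[-length(seg_dy)])
  first <- which(!same)
  last <- c(first[-1] - 1L, length(seg_t1))
  seg_t0 <- seg_t0[first]
  seg_t1 <- seg_t1[last]
  seg_item <- seg_item[first]
  seg_dy <- seg_dy[first]

  py_deg <- angle_to_px_offset(1, geometry, axis = "y")
  centers_x <- array$items$center_x_px[seg_item + 1L]
  centers_y <- array$items$center_y_px[seg_item + 1L] + seg_dy * py_deg
  if (params$gaze_noise_deg > 0) {
    centers_x <- centers_x + rnorm(length(centers_x),
                                   sd = params$gaze_noise_deg * px_deg)
    centers_y <- centers_y + rnorm(length(centers_y),
                                   sd = params$gaze_noise_deg * px_deg)
  }

  period <- 1 / params$rate_hz
  t <- seq(0, max(seg_t1) - period / 2, by = period)
  seg_of <- findInterval(t, seg_t0)
  x <- centers_x[seg_of]
  y <- centers_y[seg_of]
  lost <- runif(length(t)) < params$track_loss_frac
  samples <- tibble::tibble(
    t = t,
    lx = ifelse(lost, NA_real_, x), ly = ifelse(lost, NA_real_, y),
    lvalid = !lost,
    rx = ifelse(lost, NA_real_, x), ry = ifelse(lost, NA_real_, y),
    rvalid = !lost
  )
  trace <- gaze_trace(samples, run_spec, nominal_rate_hz = params$rate_hz)

  spoken_retained <- which(retained) - 1L
  truth <- list(
    n_perseverations = n_pers, n_regressions = n_regr,
    pers_trials = pers_trials, regr_trials = regr_trials,
    per_onset = tibble::tibble(
      serial_spoken = spoken_retained,
      true_lead = targets[spoken_retained + 1L] - spoken_retained
    ),
    naming_time = offsets[n_items] - onsets[1],
    n_errors = sum(err_draw),
    segments = tibble::tibble(item = seg_item, t0 = seg_t0, t1 = seg_t1)
  )
  list(trace = trace, track = track, truth = truth)
}

#' Simulate a diagnosis x culture cohort
#'
#' Generates per-participant run metrics for all 8 runs (4 stimulus types x
#' 2 runs) of a cohort with groups defined by culture and diagnosis, with
#' demographic covariates (age, sex, IQ, and ADOS severity for ASD
#' participants) drawn as pure nuisance variables carrying no effect.
#'
#' Two generative levels are offered. `level = "samples"` synthesises full
#' gaze traces and voice tracks with [simulate_run()] and scores them with
#' the real pipeline ([score_run()]) — slow but end-to-end. `level =
#' "metrics"` draws run metrics directly from the same generative model
#' (binomial refixation counts over the retained-item trials with a
#' participant-level logit-normal rate shift, lognormal naming times, the
#' injected eye lead plus small resolution jitter) — fast, and suited to
#' replicated power or null studies of the group-model layer.
#'
#' @param group_params Named list mapping group names of the form
#'   `"<culture>_<diagnosis>"` (e.g. `"HK_ASD"`, `"US_control"`) to
#'   [sim_params()] objects. Group effects are injected via parameter
#'   offsets between entries.
#' @param n_per_group Participants per group: a single count or a named
#'   vector aligned with `group_params`.
#' @param level `"metrics"` or `"samples"` (see above).
#' @param seed Integer seed for the whole cohort.
#' @param participant_sd_logit SD of the participant-level logit shift on
#'   the refixation probabilities (metrics level).
#' @param geometry,qc Passed to the pipeline at `level = "samples"`.
#' @return List with `run_metrics` (tibble, one row per run including
#'   demographics and QC verdicts), `participants`, and `ground_truth`
#'   (per-run injected counts and trials).
#' @export
simulate_cohort <- function(group_params, n_per_group,
                            level = c("metrics", "samples"),
                            seed = NULL,
                            participant_sd_logit = 0.3,
                            geometry = screen_geometry(),
                            qc = qc_params()) {
  level <- match.arg(level)
  if (length(group_params) < 2) stop("need at least 2 groups", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (length(n_per_group) == 1L) {
    n_per_group <- stats::setNames(rep(n_per_group, length(group_params)),
                                   names(group_params))
  }
  retained <- positional_exclusion_mask(36L, qc)
  stim_types <- .stimulus_types
  arrays <- if (level == "samples") {
    lapply(stats::setNames(stim_types, stim_types), function(st) {
      lapply(1:2, function(r) build_array_layout(st, r, geometry))
    })
  } else NULL

  participants <- list(); metrics <- list(); truths <- list()
  pid0 <- 0L
  for (g in names(group_params)) {
    parts <- strsplit(g, "_", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop("group names must be '<culture>_<diagnosis>', got: ", g,
           call. = FALSE)
    }
    culture <- parts[1]; diagnosis <- parts[2]
    gp <- group_params[[g]]
    n <- n_per_group[[g]]
    ados <- if (diagnosis == "ASD") {
      pmin(pmax(round(rnorm(n, 5.8, 2.4)), 1), 10)
    } else rep(NA_real_, n)
    part <- tibble::tibble(
      participant_id = sprintf("P%03d", pid0 + seq_len(n)),
      culture = culture, diagnosis = diagnosis,
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4)),
      age = pmin(pmax(rnorm(n, 19, 6), 10), 35),
      iq = pmin(pmax(rnorm(n, 108, 14), 80), 145),
      ados_severity = ados
    )
    pid0 <- pid0 + n
    participants[[g]] <- part
    z <- rnorm(n, 0, participant_sd_logit)
    speed <- exp(rnorm(n, 0, 0.08))
    if (level == "metrics") {
      nr <- n * 8L
      idx <- rep(seq_len(n), each = 8L)
      st <- rep(rep(stim_types, each = 2L), n)
      run <- rep(1:2, 4L * n)
      # trial counts mirror the sample-level generator's nominal
      # eligibility (30 retained gaze targets; regressions additionally
      # need a previously visited retained target)
      pers <- rbinom(nr, 30L, plogis(qlogis(gp$p_perseveration) + z)[idx])
      regr <- rbinom(nr, 29L, plogis(qlogis(gp$p_regression) + z)[idx])
      dmat <- matrix(pmax(rlnorm_mean_cv(nr * 36L,
                                         rep(gp$item_duration_mean_s *
                                               speed[idx], each = 36L),
                                         gp$item_duration_cv),
                          gp$min_item_duration_s), nrow = 36L)
      metrics[[g]] <- tibble::tibble(
        participant_id = part$participant_id[idx],
        stimulus_type = st, run_index = run,
        condition = stimulus_condition(st),
        naming_time_s = colSums(dmat) + 35 * gp$inter_item_pause_s,
        n_errors = rbinom(nr, 36L, gp$error_rate),
        mean_evs_items = round(gp$evs_lead_items) + rnorm(nr, 0, 0.03),
        n_evs_onsets = 30L,
        total_fixations = 30L + pers + regr,
        perseverations = pers, regressions = regr,
        refixations = pers + regr,
        off_array_fixations = 0L,
        track_loss_frac = gp$track_loss_frac,
        qc_pass = TRUE, qc_reasons = "",
        culture = culture, diagnosis = diagnosis,
        sex = part$sex[idx], age = part$age[idx], iq = part$iq[idx],
        ados_severity = part$ados_severity[idx]
      )
      truths[[g]] <- tibble::tibble(
        participant_id = part$participant_id[idx],
        stimulus_type = st, run_index = run,
        n_perseverations = pers, n_regressions = regr,
        pers_trials = 30L, regr_trials = 29L
      )
    } else {
      rows <- list(); trus <- list()
      for (k in seq_len(n)) {
        id <- part$participant_id[k]
        for (st in stim_types) {
          for (r in 1:2) {
            rs <- run_spec(id, st, r)
            sim <- simulate_run(gp, arrays[[st]][[r]], geometry,
                                run_spec = rs, retained = retained)
            row <- score_run(sim$trace, sim$track, arrays[[st]][[r]],
                             geometry, qc = qc)
            row$culture <- culture; row$diagnosis <- diagnosis
            row$sex <- part$sex[k]; row$age <- part$age[k]
            row$iq <- part$iq[k]; row$ados_severity <- part$ados_severity[k]
            rows[[length(rows) + 1L]] <- row
            trus[[length(trus) + 1L]] <- tibble::tibble(
              participant_id = id, stimulus_type = st, run_index = r,
              n_perseverations = sim$truth$n_perseverations,
              n_regressions = sim$truth$n_regressions,
              pers_trials = sim$truth$pers_trials,
              regr_trials = sim$truth$regr_trials
            )
          }
        }
      }
      metrics[[g]] <- dplyr::bind_rows(rows)
      truths[[g]] <- dplyr::bind_rows(trus)
    }
  }
  list(run_metrics = dplyr::bind_rows(metrics),
       participants = dplyr::bind_rows(participants),
       ground_truth = dplyr::bind_rows(truths))
}
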