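# Constructors for boundary-sweep traces: each produces a gaze trace whose
# critical quantity (inter-sample velocity, cluster gap, cluster separation,
# loss fraction, fixation-free gap) is exact by construction, so sweeps can
# locate classifier/QC boundaries at the parameter itself.

# Constant angular-velocity ramp: positions at exact angles k*v/rate from
# screen center, so the central-difference velocity is exactly v.
ramp_trace <- function(deg_per_s, rate = 60, n = 30, geo = test_geometry()) {
  k <- seq_len(n) - 1
  x <- px_at_angle_x(k * deg_per_s / rate, geo)
  gaze_trace(tibble::tibble(t = k / rate, lx = x, ly = 512, lvalid = TRUE,
                            rx = x, ry = 512, rvalid = TRUE),
             run_spec("S", "number"), rate)
}

# Two stationary clusters `sep_deg` apart with an invalid gap of `gap_ms`
# between them. With the end-of-fixation convention (last sample + period)
# the classifier-visible gap equals gap_ms exactly.
two_cluster_trace <- function(sep_deg, gap_ms, rate = 100, cluster_ms = 200,
                              geo = test_geometry()) {
  c_s <- cluster_ms / 1000
  g_s <- gap_ms / 1000
  segs <- data.frame(t0 = c(0, c_s + g_s), t1 = c(c_s + g_s, 2 * c_s + g_s),
                     x = c(px_at_angle_x(0, geo), px_at_angle_x(sep_deg, geo)),
                     y = 512)
  tr <- segment_trace(segs, rate = rate)
  bad <- which(tr$samples$t >= c_s - 1e-9 & tr$samples$t < c_s + g_s - 1e-9)
  segment_trace(segs, rate = rate, invalidate = bad)
}

# Stationary run with an exact fraction of invalidated samples.
loss_trace <- function(frac, duration_s = 20, rate = 60) {
  tr <- stationary_trace(duration_s, rate = rate)
  n <- nrow(tr$samples)
  k <- round(frac * n)
  stopifnot(abs(k - frac * n) < 1e-9)  # fraction must be exact
  tr$samples$lvalid[seq_len(k)] <- FALSE
  tr$samples$rvalid[seq_len(k)] <- FALSE
  tr$samples$lx[seq_len(k)] <- NA; tr$samples$ly[seq_len(k)] <- NA
  tr$samples$rx[seq_len(k)] <- NA; tr$samples$ry[seq_len(k)] <- NA
  tr
}

# Two 1 s fixations separated by a fixation-free (invalid) interval of
# exactly gap_s seconds.
gap_trace <- function(gap_s, rate = 60) {
  two_cluster_trace(sep_deg = 5, gap_ms = gap_s * 1000, rate = rate,
                    cluster_ms = 1000)
}

n_fix <- function(trace, geo = test_geometry()) {
  nrow(ivt_classify(trace, geo))
}
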