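# shared builders for synthetic test inputs

# window-feature rows with the provenance attributes the detector checks
fake_features <- function(mu_y, mu_z, var_y, placement = "thigh",
                          role = "NonAff") {
  f <- data.frame(window = seq_along(mu_y), t_start_s = seq_along(mu_y) - 1,
                  mu_x = 0, mu_y = mu_y, mu_z = mu_z,
                  var_x = 0, var_y = var_y, var_z = 0)
  attr(f, "placement") <- placement
  attr(f, "role") <- role
  attr(f, "window_samples") <- 50
  attr(f, "sampling_rate") <- 50
  f
}

# ramp-valued stream, handy for interpolation checks
ramp_stream <- function(t, slope = 1, side = "left", placement = "thigh") {
  sensor_stream("p1", placement, side,
                data.frame(time_s = t, ax = slope * t, ay = slope * t,
                           az = slope * t))
}

# walking-like segment signal: baseline + stride oscillation + onset pulses
pulse_signal <- function(boundaries_s, dur_s, fs = 50, amp = 6, osc = 1.8,
                         period = NULL, tau = 0.12) {
  n <- round(dur_s * fs)
  t <- (seq_len(n) - 1) / fs
  if (is.null(period)) period <- if (length(boundaries_s) > 1)
    mean(diff(boundaries_s)) else 1.2
  y <- 9.4 + osc * sin(2 * pi * t / period)
  for (tb in boundaries_s) {
    idx <- which(t >= tb - 1e-9 & t <= tb + 0.6)
    y[idx] <- y[idx] + amp * exp(-(t[idx] - tb) / tau)
  }
  y
}

# a compact scripted day: two walk bouts among sedentary activities (600 s)
short_day_script <- function(seed = 1, day_index = 1,
                             locomotion_type = "walker") {
  roll <- if (locomotion_type == "wheelchair") "wheelchair_propel" else "sit"
  day_script(data.frame(
    activity = c("sit", "walk", "stand", roll, "walk", "sit"),
    duration_s = c(120, 90, 60, 120, 90, 120)),
    seed = seed, day_index = day_index)
}
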