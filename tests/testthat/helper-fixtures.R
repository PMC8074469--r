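# shared fixture builders; everything is generated in code at test time

# recording whose six channels are supplied signals (recycled); 100 Hz default
make_recording <- function(accel_x, accel_y = accel_x, accel_z = accel_x,
                           rot = accel_x, n = length(accel_x), rate = 100,
                           patient = "p1", test = "rest", hand = "left") {
  t <- (seq_len(n) - 1) / rate
  recording(patient, test, hand, t,
            accel = cbind(rep_len(accel_x, n), rep_len(accel_y, n),
                          rep_len(accel_z, n)),
            rot_speed = cbind(rep_len(rot, n), rep_len(rot, n),
                              rep_len(rot, n)),
            sample_rate = rate)
}

sine_recording <- function(freq = 9, n = 1000, rate = 100, amp = 1, ...) {
  t <- (seq_len(n) - 1) / rate
  make_recording(amp * sin(2 * pi * freq * t), n = n, rate = rate, ...)
}

# planted two-regime truth: locally intersecting lines (tent) so the blend is
# smooth and the rule parameters are identifiable
tent_truth <- function(sigma = 0.15) {
  ts_model("x", list(
    ts_rule(list(x = gaussian_set(0.25, sigma, "low")), c(x = 1), 1),
    ts_rule(list(x = gaussian_set(0.75, sigma, "high")), c(x = -1), 2)))
}

# two-input tent on x1 (x2 carries no signal), on a severity-like scale
tent_truth_2d <- function() {
  ts_model(c("x1", "x2"), list(
    ts_rule(list(x1 = gaussian_set(0.25, 0.15, "low"),
                 x2 = gaussian_set(0.5, 0.3, "medium")),
            c(x1 = 40, x2 = 0), 10),
    ts_rule(list(x1 = gaussian_set(0.75, 0.15, "high"),
                 x2 = gaussian_set(0.5, 0.3, "medium")),
            c(x1 = -40, x2 = 0), 50)))
}

# small, fast generator configuration for module-level pipeline tests
quick_cfg <- function(n_patients = 8L, duration = 12, seed = 1L) {
  generator_config(n_patients = n_patients, duration = duration, seed = seed)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "fuzzytremor", mustWork = TRUE)
}

# force the parsed reference rules into a state where rule `fire` has firing
# degree one at the origin and every other rule fires zero there
force_rule_at_origin <- function(model, fire = 1L) {
  for (j in seq_along(model$rules)) {
    for (v in model$variables) {
      if (is.null(model$rules[[j]]$sets[[v]])) next
      set <- if (j == fire) gaussian_set(0, 1, "low")
             else gaussian_set(50, 0.01, "high")
      model <- set_rule_antecedent(model, j, v, set)
    }
  }
  model
}
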