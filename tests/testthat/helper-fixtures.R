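# Shared fixtures, built in code at test time.

test_profile <- function(id = "S1", stature = 170) {
  subject_profile(id, age = 25, sex = "M", stature_cm = stature,
                  mass_kg = 70, activity_min_week = 200)
}

# A small random recording (not a protocol capture): random smooth-ish
# coordinates with strictly increasing times. Fast enough to generate
# hundreds for round-trip properties.
random_recording <- function(n = 12, seed = 1) {
  set.seed(seed)
  body <- matrix(round(rnorm(n * 60, 0, 1), 6), n, 60)
  colnames(body) <- joint_columns()
  frames <- cbind(data.frame(frame = 0:(n - 1),
                             time_s = round(cumsum(runif(n, 0.02, 0.05)), 6)),
                  as.data.frame(body))
  recording(sprintf("R%03d", seed), sample(1:3, 1), frames,
            nominal_rate = 30)
}

# One full-protocol simulation per (seed, noise) pair, memoized: several
# test files reuse the same simulated series.
local({
  cache <- new.env()
  sim_protocol <<- function(seed = 3, noisy = FALSE, jitter = 0,
                            script = NULL) {
    key <- paste(seed, noisy, jitter, is.null(script))
    if (is.null(cache[[key]])) {
      sc <- if (is.null(script))
        update_script(motion_script(), fnt_jitter_sd = jitter) else script
      sensor <- if (noisy) sensor_model() else noiseless_sensor()
      cache[[key]] <- simulate_recording(test_profile(), sc, sensor,
                                         seed = seed)
    }
    cache[[key]]
  }
})

# A still recording (rest pose by default), optionally with another
# pose or per-column overrides; handy for detector nulls and statics.
still_recording <- function(duration = 12, rate = 30, overrides = list(),
                            pose = NULL) {
  P0 <- if (is.null(pose)) canonical_skeleton(1.70) else pose
  n <- duration * rate
  body <- matrix(rep(as.vector(t(P0)), each = n), n, 60)
  colnames(body) <- joint_columns()
  frames <- cbind(data.frame(frame = 0:(n - 1), time_s = (0:(n - 1)) / rate),
                  as.data.frame(body))
  for (nm in names(overrides)) frames[[nm]] <- overrides[[nm]]
  recording("STILL", 1, frames, nominal_rate = rate)
}
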