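# Shared fixtures: analytic TACs and small imaging set-ups built in code.

# Noiseless TAC whose frame values are the exact time-average of
# A0 * exp(-lambda t) over each frame (what the simulator + extraction
# produce for a point source, without going through the image).
analytic_tac <- function(lambda, A0 = 1, protocol = acquisition_protocol(),
                         decay_corrected = TRUE) {
  vals <- vapply(seq_len(nrow(protocol)), function(f) {
    if (lambda == 0) return(A0)
    t0 <- protocol$t_start[f]
    t1 <- protocol$t_end[f]
    A0 * (exp(-lambda * t0) - exp(-lambda * t1)) / (lambda * protocol$duration[f])
  }, numeric(1))
  as_tac(
    data.frame(frame = protocol$frame, t_start = protocol$t_start,
               duration = protocol$duration, value = vals),
    decay_corrected = decay_corrected
  )
}

# Small scanner for fast imaging tests.
small_scanner <- function(...) {
  scanner_model(voxel_size = 0.5, grid_shape = c(24L, 24L, 24L), ...)
}

# One noiseless series for a mono-exponential source.
small_series <- function(lambda = 0, A0 = 1e6, scanner = small_scanner(),
                         injection = injection_spec(activity = A0),
                         protocol = acquisition_protocol(),
                         include_physical_decay = FALSE, noise = FALSE,
                         seed = NULL) {
  p <- two_component_params(lambda_tiss = lambda, lambda_wash = 0, A0 = A0)
  act <- frame_average_activity(p, "dead", protocol,
                                include_physical_decay = include_physical_decay)
  render_frames(act, scanner, injection, protocol, noise = noise, seed = seed)
}
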