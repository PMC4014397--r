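# Shared fixtures built in code.

# A well series with exponential growth and a linear GFP ramp.
toy_series <- function(n = 20, dt = 8, fluo = NULL, od = NULL,
                       promoter = "pX", conditions = "A", day = 1L,
                       control = FALSE) {
  t <- seq(0, by = dt, length.out = n)
  if (is.null(od)) od <- 0.01 * 2^(t / 60)
  if (is.null(fluo)) fluo <- 2 * t
  plate_series(paste0("w_", promoter, "_", condition_key(condition_set(conditions)),
                      "_", day),
               promoter, conditions, day, t, od, fluo,
               is_background_control = control)
}

# Two orthogonal activity shapes on a generation grid.
toy_shapes <- function(n = 60) {
  g <- seq(0, 6, length.out = n)
  list(g = g,
       s1 = sin(pi * g / 6),          # half-sine
       s2 = cos(pi * g / 6))          # orthogonal on the symmetric grid
}

as_curve <- function(values, g, promoter = "pX", conditions = "A", day = 1L) {
  activity_curve(promoter, conditions, day, g, values, time_min = seq_along(g))
}

# Default-scale simulated experiment shared across expensive tests
# (lazy-initialized once per test run).
.shared <- new.env()
shared_pipeline <- function() {
  if (is.null(.shared$st))
    .shared$st <- run_pipeline(pipeline_config(), out = NULL, seed = 401)
  .shared$st
}
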