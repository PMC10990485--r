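# Shared fixtures: schedules are deterministic given a seed, so build the
# commonly used ones once per test run.

sched_1a <- build_schedule("1a", seed = 101)
sched_2a <- build_schedule("2a", seed = 101)

# A small simulated participant for a given generating model.
agent_data <- function(model, beta = 0.05, schedule = sched_1a, seed = 7) {
  simulate_participant(model, beta, schedule, seed = seed)
}

# Brute-force oracle: walk a rotated template from every in-square start and
# return the quadruplet positions, independent of quad realisation code.
walk_template_oracle <- function(category, rotation, anchor) {
  tmpl <- rotate_template(canonical_templates()[[as.character(category)]], rotation)
  for (si in 0:1) for (sj in 0:1) {
    pos <- matrix(NA_integer_, 4, 2)
    pos[1, ] <- c(anchor[1] + si, anchor[2] + sj)
    ok <- TRUE
    for (t in 1:3) {
      pos[t + 1, ] <- pos[t, ] + tmpl[t, ]
      if (any(pos[t + 1, ] < anchor) || any(pos[t + 1, ] > anchor + 1L)) {
        ok <- FALSE
        break
      }
    }
    if (ok && nrow(unique(pos)) == 4) return(pos)
  }
  stop("oracle found no valid walk")
}
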