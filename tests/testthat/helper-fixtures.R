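# shared fixtures built in code

# a small trace with hand-chosen samples for direct-indexing checks
toy_trace <- function() {
  sc_trace(time = seq(0, 3, by = 0.5),
           conductance = c(5.0, 5.2, 5.1, 6.0, 6.5, 6.2, 5.9),
           sampling_rate = 2)
}

# step observer: correct iff level >= cut (guess 0, effectively deterministic
# away from the cut)
step_observer <- function(cut) {
  observer_spec(threshold = cut - 0.5, spread = 1e-9, guess_rate = 0,
                lapse_rate = 0)
}

# independent straight-line re-implementation of the 2-down/1-up rules,
# table-driven: consumes a fixed response sequence and returns the visited
# levels and reversal values (oracle for staircase_step)
oracle_updown <- function(levels, start_idx, responses) {
  idx <- start_idx
  cc <- 0
  last_dir <- 0 # 0 none, -1 down, +1 up
  visited <- numeric(0)
  reversals <- numeric(0)
  for (r in responses) {
    visited <- c(visited, levels[idx])
    if (r) {
      cc <- cc + 1
      if (cc == 2) {
        cc <- 0
        if (idx > 1) {
          if (last_dir == +1) reversals <- c(reversals, levels[idx])
          last_dir <- -1
          idx <- idx - 1
        }
      }
    } else {
      cc <- 0
      if (idx < length(levels)) {
        if (last_dir == -1) reversals <- c(reversals, levels[idx])
        last_dir <- +1
        idx <- idx + 1
      }
    }
  }
  list(visited = visited, reversals = reversals)
}
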