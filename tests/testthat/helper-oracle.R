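# Independent brute-force re-implementation of the iterative background
# threshold, written as a literal loop with no shared code, used as the
# oracle for equivalence testing.
brute_force_threshold <- function(counts, k_sigma = 3,
                                  sd_estimator = c("poisson", "sample")) {
  sd_estimator <- match.arg(sd_estimator)
  bg <- seq_along(counts)
  iterations <- 0
  repeat {
    iterations <- iterations + 1
    m <- sum(counts[bg]) / length(bg)
    s <- if (sd_estimator == "poisson") {
      sqrt(m)
    } else {
      sqrt(sum((counts[bg] - m)^2) / (length(bg) - 1))
    }
    thr <- m + k_sigma * s
    keep <- c()
    removed_any <- FALSE
    for (i in bg) {
      if (counts[i] > thr) removed_any <- TRUE else keep <- c(keep, i)
    }
    if (!removed_any) {
      return(list(mean = m, sd = s, threshold = thr,
                  iterations = iterations, background_indices = bg))
    }
    bg <- keep
  }
}

# Random background + injected spike traces for oracle equivalence tests.
make_spiky_trace <- function(n, lambda, n_spikes, spike_scale = 30) {
  counts <- rpois(n, lambda)
  if (n_spikes > 0) {
    at <- sample.int(n, n_spikes)
    counts[at] <- counts[at] +
      rpois(n_spikes, spike_scale * (lambda + 5))
  }
  icp_trace(counts, dwell_time_s = 0.003)
}

study_config <- function(seed, ...) {
  update_config(sim_config(seed = seed), ...)
}
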