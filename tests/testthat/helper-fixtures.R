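# Shared fixtures, built once per test run and cached.
# Sizes are chosen so the whole suite stays fast while every stage still has
# enough positive frames (>= 10 per neuron) to exercise the 10-fold CV.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# a 300 s self-initiated session (behavior only)
fx_behavior <- function() {
  fixture("behavior", function() {
    simulate_behavior(task_config(), 300, skill = 0.8, seed = 42)
  })
}

fx_basis <- function() {
  fixture("basis", function() gaussian_basis(30))
}

fx_design <- function() {
  fixture("design", function() expand_design(fx_behavior()$behavior, fx_basis()))
}

# the behavior session with 8 neurons: 4 lever-driven stable, 4 pure noise
fx_session <- function() {
  fixture("session", function() {
    b <- fx_behavior()
    d <- fx_design()
    truth <- make_ground_truth(
      8, d,
      labels = c(rep("stable", 4), rep("noise", 4)),
      rate = 0.015, snr = 2, seed = 9
    )
    b$activity <- simulate_activity(b, truth, d, seed = 10)
    b$truth <- truth
    b$pursued <- rep(TRUE, 8)
    b$session_id <- "FIX"
    b
  })
}

# full-model encodings of the fixture session (the expensive shared fixture)
fx_encoding <- function() {
  fixture("encoding", function() {
    encode_session(fx_session(), fx_design(), seed = 77)
  })
}
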