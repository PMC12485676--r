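# Shared fixtures, built once per test run.  Everything is generated in
# code; no binary fixtures.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env))
    assign(name, build(), envir = fixture_env)
  get(name, envir = fixture_env)
}

toy_dimer <- function() fixture("toy_dimer", function() make_toy_dimer(1))

# single-protofilament, 3-ring periodic lattice with alpha tails: the
# standard topology for trajectory-analysis tests
tailed_lattice <- function() fixture("tailed_lattice", function() {
  lat <- make_toy_lattice(n_pf = 1, n_rings = 3)
  model <- append_tails(lat$model, seed = 2)
  list(model = make_infinite(model, lat$spec), spec = lat$spec)
})

# a short planted simulation shared across contact/synthetic tests
short_sim <- function() fixture("short_sim", function() {
  kin <- kinetics_preset("gdp_like", n_frames = 400)
  sim <- simulate_binding(kin, tailed_lattice()$model, seed = 11)
  sim$kinetics <- kin
  sim$timeline <- build_timeline(sim$trajectory)
  sim
})
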