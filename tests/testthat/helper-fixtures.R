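# Shared fixtures, computed once per test run. All fixtures are built in
# code from the package's own simulators; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

fitted_params <- function() model_params()

fx_traj <- function() fx("traj", function()
  simulate_free_running(fitted_params(), duration = 30, thin = 5L))

fx_cycle <- function() fx("cycle", function()
  extract_limit_cycle(fx_traj()))

fx_reference <- function() fx("reference", function()
  oscillator_reference(fitted_params(), thin = 10L))

fx_prc64 <- function() fx("prc64", function()
  model_prc(fitted_params(), inhibition_spec(), n_phases = 64L,
            reference = fx_reference()))
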