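# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# moderate-size noiseless planted dataset + trained ensemble
fx_dataset <- function() fixture("dataset", function()
  generate_dataset(rule_set(label_noise = 0), n = 1500, seed = 42))

fx_model <- function() fixture("model", function() {
  d <- fx_dataset()
  agn_ensemble(d$data$sequence, d$data$label, seed = 42)
})
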