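# Shared fixtures: a fast output grid for tests that do not probe quadrature
# accuracy, and a cache so repeated nominal simulations are free.
fast_settings <- sim_settings(output_dt = 0.1)

test_cache <- new_sim_cache()

sim_cached <- function(profile, settings = fast_settings, model = "coincidence") {
  evaluate_profile_row(profile, settings, get_clock_model(model),
                       phenotype_params(), energy_params(), test_cache)
}

# evaluate_profile_row is internal; reach it for the helper only
evaluate_profile_row <- greenlight:::evaluate_profile_row
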