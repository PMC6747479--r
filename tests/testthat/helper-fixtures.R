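# Shared fixtures built in code.

field_14t <- function() field_spec(proton_frequency = 599.98e6)

# the exchange regime measured for the loaded zwitterionic micelle
paper_exchange <- function() {
  exchange_params(p_b = 0.028, k_ex = 253, delta_omega = 5.2e3,
                  r2_a = 31.25, r2_b = 5.26)
}

noiseless_echo <- function(i0 = 1000, d = 8e-11, nuc = "1H",
                           delta = 4e-3, big_delta = 40e-3,
                           gradients = schedule_preset("pgse_1h_25")) {
  tibble::tibble(gradient = gradients,
                 amplitude = st_signal(gradients, i0, d, nuc, delta, big_delta))
}

noiseless_decay <- function(rate, times, i0 = 100) {
  tibble::tibble(time = times, amplitude = i0 * exp(-rate * times))
}
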