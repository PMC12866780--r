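# Shared fixtures built in code.

# Reference viscoelastic parameter set used across tests (matches the
# gen_relaxation default).
ref_visco <- function() visco_params(1000, 2, 500, 150, 1500)

# Small indentation record with a known constant force within every hold.
const_force_series <- function(value = 2e-6, protocol = indentation_protocol(),
                               H0 = 3e-3, rate = 10) {
  tl <- mechisto:::protocol_timeline(protocol)
  time <- seq(0, max(tl$hold_end), by = 1 / rate)
  mech_series(time, force = rep(value, length(time)), H0 = H0)
}

# Greedy matched-label agreement between predicted and true labelings.
label_agreement <- function(pred, truth) {
  tab <- table(pred, truth)
  sum(apply(tab, 2, max)) / length(truth)
}
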