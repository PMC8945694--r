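# shared fixtures: one aerated and one non-aerated synthetic respirogram,
# built once per test run
lab <- kinetic_preset("lab")

resp_aerated_57 <- generate_respirogram(
  pulse_config(csi = 57, xa = 1, seed = 42), lab
)

resp_nonaer_15 <- generate_respirogram(
  pulse_config(csi = 15, xa = 1, aerated = FALSE, ka_true = 0, seed = 7), lab
)

# small process configuration used by fast simulator tests
small_process <- function(...) {
  args <- modifyList(
    list(kinetics = lab, n_elements = 2000, t_end = 15,
         record_every_s = 5, seed = 99),
    list(...)
  )
  do.call(process_config, args)
}
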