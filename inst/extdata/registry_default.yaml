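# Default additive-rate registry for the nine-sample composition study.
# Rates in s^-1, correlation times in seconds, delta_sigma in ppm.
# provenance: paper = tabulated experimental value; derived = arithmetic on
# tabulated values; decision = package default where nothing is tabulated.
mechanisms:
  background:
    rate: 0.0044
    sd: 0.0001
    provenance: paper
  intraDD:
    rate: 0.0008
    sd: 0.0002
    channel: intra
    provenance: paper
  interDD:
    rate: 0.0095          # variant measured in a chelated context: 0.0076
    sd: 0.0006
    channel: inter
    variant: default
    provenance: paper
  pre_o2:
    amplitude: 0.0066     # low-field O2 PRE, from 1/84.2 - 1/188.0 s^-1
    tau_c: 6.1e-12
    tau_c_sd: 2.0e-12
    provenance: derived
  pre_metal:
    amplitude_h2o: 0.0133
    amplitude_d2o: 0.0113
    sd_h2o: 0.0005
    sd_d2o: 0.0004
    tau_c: 2.0e-10        # "hundreds of picoseconds"; exact value a decision
    provenance: paper
    tau_c_provenance: decision
  csa:
    delta_sigma: 136.5
    delta_sigma_sd: 1.6
    tau_c: 7.3e-12
    provenance: paper
  radical:
    amplitude: 0.002      # placeholder, refit from data; no tabulated value
    tau_c: 2.0e-10
    provenance: decision
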