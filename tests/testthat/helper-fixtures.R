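# Shared fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

# Noiseless nine-sample bundle under the default registry.
noiseless_bundle <- function() {
  if (is.null(.fixtures$clean))
    .fixtures$clean <- generate_study_bundle(noise_rel = 0)
  .fixtures$clean
}

# A tabulated constant-T1 relaxation map (field-independent).
flat_map <- function(T1) {
  relaxation_map(profile = nmrd_profile("flat", B0 = c(1e-5, 1e-2, 10),
                                        T1 = rep(T1, 3)))
}
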