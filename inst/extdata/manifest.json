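{
  "file": "monthly_transitions_synthetic_registry2022.csv",
  "preset": "registry2022",
  "seed": 2022,
  "note": "Synthetic monthly transition probabilities generated by waitlistsim::generate_parameter_set(2022, \"registry2022\"); anchored to 2022 US registry magnitudes, not estimated from microdata.",
  "package_version": "0.1.0"
}
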