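# builders shared across test files

quiet_optics <- function(sleeve_id = "s1", led_power = 2L) {
  true_optics(sleeve_id, led_power = led_power, noise_sd = 0)
}

noisy_optics <- function(sleeve_id = "s1", led_power = 2L, noise_sd = 50) {
  true_optics(sleeve_id, led_power = led_power, noise_sd = noise_sd)
}

fixed_vial <- function(vial_id = "v1", glass_offset = 0, rotation_sd = 100,
                       volume_ml = 25, influx_efficiency = 1) {
  true_vial(vial_id, glass_offset = glass_offset, rotation_sd = rotation_sd,
            volume_ml = volume_ml, influx_efficiency = influx_efficiency)
}

# exact noise-free calibration of a sleeve/vial pairing
exact_curve <- function(optics = quiet_optics(), vial = fixed_vial()) {
  calibrate_sleeve(optics, vial, spectro_sd = 0)
}

# medium blank of a quiet rig (no noise: the blank equals g(0) + offset)
exact_blank <- function(optics = quiet_optics(), vial = fixed_vial()) {
  record_blank(vial$vial_id, rep(measure_raw(optics, vial, NULL, 1), 3))
}
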