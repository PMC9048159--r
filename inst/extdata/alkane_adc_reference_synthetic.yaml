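# SYNTHETIC default reference ADC table for the alkane diffusion vials.
#
# Values are representative of published self-diffusion magnitudes for
# n-nonane, n-undecane and n-tridecane (free-diffusion liquids with ADC
# decreasing with chain length and increasing ~2-3% per deg C), tabulated
# here on a 15-30 deg C grid for linear interpolation. They are a synthetic
# stand-in: replace this file with site-validated literature values before
# using the ADC accuracy test on real scanner data.
#
# Units: temperature_C in deg C, adc_mm2s in mm^2/s.
nonane:
  temperature_C: [15.0, 18.0, 21.0, 24.0, 27.0, 30.0]
  adc_mm2s: [1.42e-3, 1.53e-3, 1.65e-3, 1.77e-3, 1.90e-3, 2.03e-3]
undecane:
  temperature_C: [15.0, 18.0, 21.0, 24.0, 27.0, 30.0]
  adc_mm2s: [0.92e-3, 1.00e-3, 1.08e-3, 1.17e-3, 1.26e-3, 1.35e-3]
tridecane:
  temperature_C: [15.0, 18.0, 21.0, 24.0, 27.0, 30.0]
  adc_mm2s: [0.64e-3, 0.70e-3, 0.76e-3, 0.82e-3, 0.89e-3, 0.96e-3]
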