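# Preset family models: one log-linear psychophysical law OI = k*ln(OAV) + b
# and one mixture slope s (OI_mix = s * OI_sum) per odorant family.
# The interaction coefficient cos(alpha) is never stored: it is derived from
# the slope at load time as cos(alpha) = 2*s^2 - 1.
aldehydes:
  k: 5.6
  b: -5.6
  slope: 0.62
  members: [Acetaldehyde, Propionaldehyde, n-Butyraldehyde]
  oirs:
    base_ppm: 10
    ratio: 2
    n_levels: 12
esters:
  k: 1.4
  b: -2.7
  slope: 0.79
  members: [Ethyl acetate, Butyl acetate, Ethyl butyrate]
  oirs:
    base_ppm: 12
    ratio: 2
    n_levels: 8
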