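# Parameter sets for the visual-model sensitivity analysis.
#
# The `average` entries are the standard average UVS / VS avian visual
# systems. Extreme (min/max) pigment, oil-droplet and most density entries
# are editable placeholders spanning ranges reported in the avian
# microspectrophotometry literature; they are marked `placeholder: true` and
# sweeps refuse to use them unless explicitly allowed
# (`allow_placeholders = TRUE`). Replace them with measured values before
# drawing biological conclusions.
#
# Units: lambda_max, lambda_cut, t50 in nm; b_mid per nm; densities are
# relative abundances SWS1:SWS2:MWS:LWS.

illuminants: [ideal, forest_shade, woodland_shade, blue_sky, d65, woodland_gaps, cloudy_sky]

uvs:
  t50: [314, 324, 334, 344]
  lambda_max:
    average: {SWS1: 367, SWS2: 444, MWS: 501, LWS: 564}
    min: {SWS1: 355, SWS2: 430, MWS: 497, LWS: 543}
    max: {SWS1: 380, SWS2: 463, MWS: 509, LWS: 571}
    placeholder: true
  droplets:
    average:
      SWS2: {lambda_cut: 411, b_mid: 0.0278}
      MWS: {lambda_cut: 511, b_mid: 0.023}
      LWS: {lambda_cut: 572, b_mid: 0.022}
    min:
      SWS2: {lambda_cut: 396, b_mid: 0.031}
      MWS: {lambda_cut: 492, b_mid: 0.027}
      LWS: {lambda_cut: 551, b_mid: 0.026}
    max:
      SWS2: {lambda_cut: 436, b_mid: 0.025}
      MWS: {lambda_cut: 528, b_mid: 0.020}
      LWS: {lambda_cut: 594, b_mid: 0.018}
    placeholder: true

vs:
  t50: [335, 355, 375, 395]
  lambda_max:
    average: {SWS1: 412, SWS2: 452, MWS: 505, LWS: 565}
    min: {SWS1: 402, SWS2: 440, MWS: 497, LWS: 543}
    max: {SWS1: 426, SWS2: 463, MWS: 509, LWS: 571}
    placeholder: true
  droplets:
    average:
      SWS2: {lambda_cut: 447, b_mid: 0.0294}
      MWS: {lambda_cut: 510, b_mid: 0.028}
      LWS: {lambda_cut: 570, b_mid: 0.020}
    min:
      SWS2: {lambda_cut: 430, b_mid: 0.032}
      MWS: {lambda_cut: 490, b_mid: 0.030}
      LWS: {lambda_cut: 552, b_mid: 0.024}
    max:
      SWS2: {lambda_cut: 460, b_mid: 0.026}
      MWS: {lambda_cut: 526, b_mid: 0.024}
      LWS: {lambda_cut: 588, b_mid: 0.017}
    placeholder: true

densities:
  pekin_robin: {values: [1, 2, 2, 4], placeholder: false}
  anous_minutus: {values: [1, 9.59, 16.82, 14.29], placeholder: false}
  puffinus_pacificus: {values: [1, 0.68, 1.04, 1.44], placeholder: false}
  sturnus_vulgaris: {values: [1, 1.71, 2.24, 2.12], placeholder: true}
  cyanistes_caeruleus: {values: [1, 1.92, 2.68, 2.70], placeholder: true}
  gallus_gallus: {values: [1, 1.76, 2.26, 1.80], placeholder: true}
  taeniopygia_guttata: {values: [1, 1.63, 1.51, 2.51], placeholder: true}
  columba_livia: {values: [1, 1.81, 2.53, 3.35], placeholder: true}
  pavo_cristatus: {values: [1, 1.90, 2.20, 2.80], placeholder: true}
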