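# default multimodal speed table (km/h); substitute locally tracked speeds
walking:
  grassland: 5
  cropland: 4
  dense_vegetation: 2
  builtup: 5
roads:
  primary: 80
  secondary: 40
  tertiary: 20
water_impassable: true
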