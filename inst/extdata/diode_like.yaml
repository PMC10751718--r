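# Simplified silicon diode detector for the Fano cavity test.
# Water-equivalent media with original densities; dimensions in cm.
# The silicon chip volume is 3.4e-4 cm^3; origin at the chip centre.
name: diode_like
phantom: [10.0, 10.0, 12.0]
source_box: [5.0, 5.0, 7.0]
sensitive: [3]
regions:
  - {id: 0, name: water,        shape: box,      base: true, center: [0.0, 0.0, 0.0], density: 1.0}
  - {id: 1, name: housing_pmma, shape: cylinder, center: [0.0, 0.0, 0.0], radius: 0.35, half_height: 0.50, density: 1.19}
  - {id: 2, name: epoxy,        shape: cylinder, center: [0.0, 0.0, 0.0], radius: 0.28, half_height: 0.35, density: 1.20}
  - {id: 3, name: silicon_chip, shape: cylinder, center: [0.0, 0.0, 0.0], radius: 0.11, half_height: 0.00447215, density: 2.33}
  - {id: 4, name: air_gap,      shape: cylinder, center: [0.0, 0.0, 0.10], radius: 0.20, half_height: 0.025, density: 0.0012048}
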