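# Simplified thimble ionization chamber for the Fano cavity test.
# All media are water-equivalent (water mass stopping power) and differ
# only in mass density. Dimensions in cm, densities in g/cm^3.
# z is the detector symmetry axis; the origin sits at the centre of the
# sensitive air volume. The net air-cavity volume (annulus around the
# 0.04 cm radius aluminium electrode) is 0.07 cm^3.
name: chamber_like
phantom: [10.0, 10.0, 12.0]
source_box: [5.0, 5.0, 7.0]
sensitive: [3]
regions:
  - {id: 0, name: water,      shape: box,      base: true, center: [0.0, 0.0, 0.0], density: 1.0}
  - {id: 1, name: wall_pmma,  shape: cylinder, center: [0.0, 0.0, 0.0], radius: 0.35, half_height: 0.70, density: 1.19}
  - {id: 2, name: liner_graphite, shape: cylinder, center: [0.0, 0.0, 0.0], radius: 0.30, half_height: 0.60, density: 1.70}
  - {id: 3, name: air_cavity, shape: cylinder, center: [0.0, 0.0, 0.0], radius: 0.24, half_height: 0.1989435, density: 0.0012048}
  - {id: 4, name: electrode_al, shape: cylinder, center: [0.0, 0.0, 0.0], radius: 0.04, half_height: 0.1989435, density: 2.70}
  - {id: 5, name: stem_pmma,  shape: cylinder, center: [0.0, 0.0, 1.75], radius: 0.35, half_height: 1.05, density: 1.19}
  - {id: 6, name: stem_air_1, shape: cylinder, center: [0.0, 0.0, 1.00], radius: 0.25, half_height: 0.02, density: 0.0012048}
  - {id: 7, name: stem_air_2, shape: cylinder, center: [0.0, 0.0, 1.60], radius: 0.25, half_height: 0.02, density: 0.0012048}
  - {id: 8, name: stem_air_3, shape: cylinder, center: [0.0, 0.0, 2.20], radius: 0.25, half_height: 0.02, density: 0.0012048}
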