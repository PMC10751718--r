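# Three-layer sandwich (water / low-density gap / water) used as the
# oracle geometry for transport and Fano property tests. The base water
# region supplies the outer layers; an explicit lower water layer is kept
# as a separate scoring region. The gap and the lower layer lie well
# inside the source box (margin larger than the 1 MeV CSDA reach,
# including air chords), so every scoring region sees full charged
# particle equilibrium. Dimensions in cm.
name: slab
phantom: [6.0, 6.0, 6.0]
source_box: [4.0, 4.0, 4.0]
sensitive: [1]
regions:
  - {id: 0, name: water,       shape: box, base: true, center: [0.0, 0.0, 0.0], density: 1.0}
  - {id: 1, name: gap_air,     shape: box, center: [0.0, 0.0, 0.0],   size: [2.0, 2.0, 0.5], density: 0.0012048}
  - {id: 2, name: water_lower, shape: box, center: [0.0, 0.0, -0.75], size: [2.0, 2.0, 1.0], density: 1.0}
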