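# Geometry configuration schema

A geometry is a YAML document describing a box phantom (centred at the
origin) tiled by nested regions. Units: cm for lengths, g/cm^3 for
densities. The z axis is the detector symmetry axis; the magnetic field is
conventionally applied along x.

Top-level keys:

- `name` — geometry name (string).
- `phantom` — `[x, y, z]` full phantom dimensions.
- `source_box` — `[x, y, z]` recommended Fano source-box dimensions
  (centred at the origin; must lie inside the phantom).
- `sensitive` — list of region ids forming the detector's sensitive
  volume (used for efficiency reporting).
- `regions` — ordered list of regions in carve-out priority order:
  later entries carve their volume out of the innermost earlier region
  that contains them ("last-listed wins").

Each region is a mapping with:

- `id` — unique small non-negative integer.
- `name` — region name.
- `shape` — `box` or `cylinder` (finite cylinder, axis along z).
- `center` — `[x, y, z]` centre.
- `size` — `[x, y, z]` full edge lengths (box only). A box with
  `base: true` takes the phantom dimensions; the first region must be such
  a base box (the background water).
- `radius`, `half_height` — cylinder parameters.
- `density` — mass density (> 0). All media are water-equivalent: they
  share the collision mass stopping power of water and differ only in
  density, as the Fano substitution requires.

Validation on load: unique ids; the first region coincides with the
phantom; every later region is fully contained in an earlier one; regions
sharing the same parent are disjoint; all net (carved) volumes are
positive. Net volumes are closed-form, so region volumes sum exactly to
the phantom volume.
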