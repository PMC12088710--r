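# Example synthetic vessel phantom: 4.48 mm field of view at 10 um/px,
# one lipid plaque with a 90 degree arc and a 65 um cap, one calcified
# plaque, a guidewire shadow and a side branch.
spacing_mm: 0.01
frame_shape: [448, 448]
lumen_radius_mm: 1.0
intima_thickness_mm: 0.2
media_thickness_mm: 0.1
sectors:
  - plaque_class: lipid
    theta_start_deg: 30
    extent_deg: 90
    cap_thickness_mm: 0.065
    plaque_thickness_mm: 0.4
  - plaque_class: calcium
    theta_start_deg: 200
    extent_deg: 60
    cap_thickness_mm: 0.2
    plaque_thickness_mm: 0.5
guidewire: [150, 20]
side_branch: [290, 25]
seed: 1
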