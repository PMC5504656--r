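p_prolif_stem: 0.2
p_prolif_prog: 0.5
p_symmetric: 0.05
p_ccr5_convert: 0.05
p_ccr5_convert_hypoxic: 0.25
division_limit: 12
p_senescent_death: 0.1
steps_ccr5_low: 1
steps_ccr5_high: 2
max_steps_per_day: 20
hypoxia_migration_factor: 3.0
hypoxia_prolif_factor: 0.5
hypoxia_distance_um: 200.0
hypoxia_on: yes
vessel_kind: plane
vessel_anchor:
- 0
- 0
- 0
vessel_axis: x
init_counts:
- 19
- 1
- 5
- 75
dims:
- 100
- 100
- 80
voxel_size_um: 20.0
seed_offset: 3
seed_size: 8
senescent_migrate: yes
max_days: 1080
max_cells: 50000
seed: 1
maraviroc:
  enabled: no
anti_stem:
  enabled: no
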