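quantity,value
forest_type1_mean,0.029
forest_type2_mean,0.153
forest_f1_mean,0.904
bog_type1_mean,0.248
bog_type2_mean,0.139
bog_f1_mean,0.801
grassland_type1_mean,0.386
grassland_type2_mean,0.000
grassland_f1_mean,0.747
bog_persistence,0.1561
bog_to_forest,0.7942
changed_area_ha,847.7
improved_area_ha,584.0
degraded_area_ha,263.7
delta_mean,0.073
delta_median,0.053
delta_iqr,0.176
largest_patch_ha,560
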