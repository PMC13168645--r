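year,forest_ha,bog_ha,grassland_ha,forest_pct,bog_pct,grassland_pct
1984,461.8,327.9,91.8,52.39,37.19,10.41
1990,519.0,254.1,108.3,58.88,28.83,12.29
1995,565.8,259.0,56.7,64.18,29.38,6.43
2000,591.9,220.7,68.9,67.14,25.04,7.82
2005,592.3,224.7,64.5,67.19,25.49,7.32
2010,626.3,199.9,55.3,71.05,22.68,6.27
2015,641.6,187.8,52.1,72.78,21.31,5.91
2020,663.0,162.8,55.7,75.21,18.47,6.32
2024,738.4,89.8,53.3,83.77,10.19,6.04
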