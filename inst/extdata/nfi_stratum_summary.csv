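stratum,spruce_pct,pine_pct,deciduous_pct,unstocked_pct,area_km2,forest_pct,n_plots_forest,forest_area_km2
1,34.0,33.7,31.8,0.6,149885,66.4,11046,99551
2,3.6,8.1,87.8,0.5,125281,9.5,442,11906
3,0.0,64.2,35.8,0.0,1350,80.0,120,1080
4,0.0,4.2,94.9,0.8,47266,20.5,118,9683
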