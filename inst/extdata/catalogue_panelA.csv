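name,panel,channel,population,family,baseline
field_Hoechst_int_mean,panelA,Hoechst,field,intensity,1500
field_Hoechst_int_sd,panelA,Hoechst,field,intensity,450
field_Hoechst_int_p90,panelA,Hoechst,field,intensity,2250
field_aSyn_int_mean,panelA,aSyn,field,intensity,800
field_aSyn_int_sd,panelA,aSyn,field,intensity,240
field_aSyn_int_p90,panelA,aSyn,field,intensity,1200
field_TH_int_mean,panelA,TH,field,intensity,1000
field_TH_int_sd,panelA,TH,field,intensity,300
field_TH_int_p90,panelA,TH,field,intensity,1500
field_MAP2_int_mean,panelA,MAP2,field,intensity,1200
field_MAP2_int_sd,panelA,MAP2,field,intensity,360
field_MAP2_int_p90,panelA,MAP2,field,intensity,1800
field_aSyn_gran_r2,panelA,aSyn,field,texture,0.2
field_aSyn_gran_r4,panelA,aSyn,field,texture,0.35
field_MAP2_gran_r2,panelA,MAP2,field,texture,0.2
field_MAP2_gran_r4,panelA,MAP2,field,texture,0.35
field_Hoechst_gran_r2,panelA,Hoechst,field,texture,0.2
field_Hoechst_gran_r4,panelA,Hoechst,field,texture,0.35
nuclei_count,panelA,Hoechst,nuclei,count,120
nuclei_density,panelA,Hoechst,nuclei,count,0.00325520833333333
nuclei_Hoechst_int_mean,panelA,Hoechst,nuclei,intensity,1500
nuclei_Hoechst_int_median,panelA,Hoechst,nuclei,intensity,1425
nuclei_Hoechst_int_sd,panelA,Hoechst,nuclei,intensity,450
nuclei_Hoechst_int_p90,panelA,Hoechst,nuclei,intensity,2250
nuclei_area_mean,panelA,Hoechst,nuclei,morphology,80
nuclei_area_sd,panelA,Hoechst,nuclei,morphology,20
nuclei_perimeter_mean,panelA,Hoechst,nuclei,morphology,34
nuclei_perimeter_sd,panelA,Hoechst,nuclei,morphology,8.5
nuclei_form_factor_mean,panelA,Hoechst,nuclei,morphology,0.85
nuclei_form_factor_sd,panelA,Hoechst,nuclei,morphology,0.2125
nuclei_compactness_mean,panelA,Hoechst,nuclei,morphology,0.8
nuclei_compactness_sd,panelA,Hoechst,nuclei,morphology,0.2
nuclei_eccentricity_mean,panelA,Hoechst,nuclei,morphology,0.55
nuclei_eccentricity_sd,panelA,Hoechst,nuclei,morphology,0.1375
all_cells_count,panelA,MAP2,all_cells,count,90
all_cells_Hoechst_int_mean,panelA,Hoechst,all_cells,intensity,1500
all_cells_Hoechst_int_median,panelA,Hoechst,all_cells,intensity,1425
all_cells_Hoechst_int_sd,panelA,Hoechst,all_cells,intensity,450
all_cells_Hoechst_int_p90,panelA,Hoechst,all_cells,intensity,2250
all_cells_aSyn_int_mean,panelA,aSyn,all_cells,intensity,800
all_cells_aSyn_int_median,panelA,aSyn,all_cells,intensity,760
all_cells_aSyn_int_sd,panelA,aSyn,all_cells,intensity,240
all_cells_aSyn_int_p90,panelA,aSyn,all_cells,intensity,1200
all_cells_TH_int_mean,panelA,TH,all_cells,intensity,1000
all_cells_TH_int_median,panelA,TH,all_cells,intensity,950
all_cells_TH_int_sd,panelA,TH,all_cells,intensity,300
all_cells_TH_int_p90,panelA,TH,all_cells,intensity,1500
all_cells_MAP2_int_mean,panelA,MAP2,all_cells,intensity,1200
all_cells_MAP2_int_median,panelA,MAP2,all_cells,intensity,1140
all_cells_MAP2_int_sd,panelA,MAP2,all_cells,intensity,360
all_cells_MAP2_int_p90,panelA,MAP2,all_cells,intensity,1800
all_cells_area_mean,panelA,MAP2,all_cells,morphology,300
all_cells_area_sd,panelA,MAP2,all_cells,morphology,75
all_cells_perimeter_mean,panelA,MAP2,all_cells,morphology,75
all_cells_perimeter_sd,panelA,MAP2,all_cells,morphology,18.75
all_cells_form_factor_mean,panelA,MAP2,all_cells,morphology,0.6
all_cells_form_factor_sd,panelA,MAP2,all_cells,morphology,0.15
all_cells_compactness_mean,panelA,MAP2,all_cells,morphology,0.55
all_cells_compactness_sd,panelA,MAP2,all_cells,morphology,0.1375
all_cells_eccentricity_mean,panelA,MAP2,all_cells,morphology,0.65
all_cells_eccentricity_sd,panelA,MAP2,all_cells,morphology,0.1625
all_cells_ratio_aSyn_TH,panelA,aSyn,all_cells,ratio,0.8
all_cells_ratio_aSyn_MAP2,panelA,aSyn,all_cells,ratio,0.666666666666667
MAP2_pos_count,panelA,MAP2,MAP2_pos,count,60
MAP2_pos_fraction,panelA,MAP2,MAP2_pos,ratio,0.65
MAP2_pos_MAP2_int_mean,panelA,MAP2,MAP2_pos,intensity,1200
MAP2_pos_MAP2_int_sd,panelA,MAP2,MAP2_pos,intensity,360
MAP2_pos_aSyn_int_mean,panelA,aSyn,MAP2_pos,intensity,800
neurites_total_length,panelA,MAP2,neurites,morphology,4000
neurites_branch_points,panelA,MAP2,neurites,count,150
neurites_end_points,panelA,MAP2,neurites,count,180
neurites_branch_density,panelA,MAP2,neurites,ratio,0.0375
TH_pos_count,panelA,TH,TH_pos,count,35
TH_pos_fraction,panelA,TH,TH_pos,ratio,0.4
TH_pos_density,panelA,TH,TH_pos,count,0.000949435763888889
TH_pos_Hoechst_int_mean,panelA,Hoechst,TH_pos,intensity,1500
TH_pos_Hoechst_int_median,panelA,Hoechst,TH_pos,intensity,1425
TH_pos_Hoechst_int_sd,panelA,Hoechst,TH_pos,intensity,450
TH_pos_Hoechst_int_p90,panelA,Hoechst,TH_pos,intensity,2250
TH_pos_Hoechst_int_total,panelA,Hoechst,TH_pos,intensity,450000
TH_pos_aSyn_int_mean,panelA,aSyn,TH_pos,intensity,800
TH_pos_aSyn_int_median,panelA,aSyn,TH_pos,intensity,760
TH_pos_aSyn_int_sd,panelA,aSyn,TH_pos,intensity,240
TH_pos_aSyn_int_p90,panelA,aSyn,TH_pos,intensity,1200
TH_pos_aSyn_int_total,panelA,aSyn,TH_pos,intensity,240000
TH_pos_TH_int_mean,panelA,TH,TH_pos,intensity,1000
TH_pos_TH_int_median,panelA,TH,TH_pos,intensity,950
TH_pos_TH_int_sd,panelA,TH,TH_pos,intensity,300
TH_pos_TH_int_p90,panelA,TH,TH_pos,intensity,1500
TH_pos_TH_int_total,panelA,TH,TH_pos,intensity,3e+05
TH_pos_MAP2_int_mean,panelA,MAP2,TH_pos,intensity,1200
TH_pos_MAP2_int_median,panelA,MAP2,TH_pos,intensity,1140
TH_pos_MAP2_int_sd,panelA,MAP2,TH_pos,intensity,360
TH_pos_MAP2_int_p90,panelA,MAP2,TH_pos,intensity,1800
TH_pos_MAP2_int_total,panelA,MAP2,TH_pos,intensity,360000
TH_pos_area_mean,panelA,TH,TH_pos,morphology,300
TH_pos_area_median,panelA,TH,TH_pos,morphology,291
TH_pos_area_sd,panelA,TH,TH_pos,morphology,75
TH_pos_perimeter_mean,panelA,TH,TH_pos,morphology,75
TH_pos_perimeter_median,panelA,TH,TH_pos,morphology,72.75
TH_pos_perimeter_sd,panelA,TH,TH_pos,morphology,18.75
TH_pos_form_factor_mean,panelA,TH,TH_pos,morphology,0.6
TH_pos_form_factor_median,panelA,TH,TH_pos,morphology,0.582
TH_pos_form_factor_sd,panelA,TH,TH_pos,morphology,0.15
TH_pos_compactness_mean,panelA,TH,TH_pos,morphology,0.55
TH_pos_compactness_median,panelA,TH,TH_pos,morphology,0.5335
TH_pos_compactness_sd,panelA,TH,TH_pos,morphology,0.1375
TH_pos_eccentricity_mean,panelA,TH,TH_pos,morphology,0.65
TH_pos_eccentricity_median,panelA,TH,TH_pos,morphology,0.6305
TH_pos_eccentricity_sd,panelA,TH,TH_pos,morphology,0.1625
TH_pos_neurite_length_per_cell,panelA,TH,TH_pos,morphology,120
TH_pos_neurite_branch_points_per_cell,panelA,TH,TH_pos,count,4
TH_pos_neurite_end_points_per_cell,panelA,TH,TH_pos,count,5
TH_pos_neurite_branch_density,panelA,TH,TH_pos,ratio,0.0333333333333333
TH_pos_agg_count_per_cell,panelA,aSyn,TH_pos,count,3
TH_pos_agg_area_mean,panelA,aSyn,TH_pos,morphology,6
TH_pos_agg_area_total_per_cell,panelA,aSyn,TH_pos,morphology,18
TH_pos_agg_int_mean,panelA,aSyn,TH_pos,intensity,1400
TH_pos_ratio_aSyn_TH,panelA,aSyn,TH_pos,ratio,0.8
TH_pos_ratio_aSyn_MAP2,panelA,aSyn,TH_pos,ratio,0.666666666666667
TH_pos_ratio_TH_MAP2,panelA,TH,TH_pos,ratio,0.833333333333333
TH_pos_ratio_aSyn_Hoechst,panelA,aSyn,TH_pos,ratio,0.533333333333333
TH_pos_aSyn_gran_r2,panelA,aSyn,TH_pos,texture,0.2
TH_pos_aSyn_gran_r4,panelA,aSyn,TH_pos,texture,0.35
TH_pos_TH_gran_r2,panelA,TH,TH_pos,texture,0.2
TH_pos_TH_gran_r4,panelA,TH,TH_pos,texture,0.35
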