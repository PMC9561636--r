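name,panel,channel,population,family,baseline
field_Hoechst_int_mean,panelLAMP1,Hoechst,field,intensity,1500
field_Hoechst_int_sd,panelLAMP1,Hoechst,field,intensity,450
field_Hoechst_int_p90,panelLAMP1,Hoechst,field,intensity,2250
field_aSyn_int_mean,panelLAMP1,aSyn,field,intensity,800
field_aSyn_int_sd,panelLAMP1,aSyn,field,intensity,240
field_aSyn_int_p90,panelLAMP1,aSyn,field,intensity,1200
field_LAMP1_int_mean,panelLAMP1,LAMP1,field,intensity,700
field_LAMP1_int_sd,panelLAMP1,LAMP1,field,intensity,210
field_LAMP1_int_p90,panelLAMP1,LAMP1,field,intensity,1050
field_MAP2_int_mean,panelLAMP1,MAP2,field,intensity,1200
field_MAP2_int_sd,panelLAMP1,MAP2,field,intensity,360
field_MAP2_int_p90,panelLAMP1,MAP2,field,intensity,1800
field_aSyn_gran_r2,panelLAMP1,aSyn,field,texture,0.2
field_aSyn_gran_r4,panelLAMP1,aSyn,field,texture,0.35
field_LAMP1_gran_r2,panelLAMP1,LAMP1,field,texture,0.2
field_LAMP1_gran_r4,panelLAMP1,LAMP1,field,texture,0.35
nuclei_count,panelLAMP1,Hoechst,nuclei,count,120
nuclei_density,panelLAMP1,Hoechst,nuclei,count,0.00325520833333333
nuclei_Hoechst_int_mean,panelLAMP1,Hoechst,nuclei,intensity,1500
nuclei_Hoechst_int_median,panelLAMP1,Hoechst,nuclei,intensity,1425
nuclei_Hoechst_int_sd,panelLAMP1,Hoechst,nuclei,intensity,450
nuclei_Hoechst_int_p90,panelLAMP1,Hoechst,nuclei,intensity,2250
nuclei_area_mean,panelLAMP1,Hoechst,nuclei,morphology,80
nuclei_area_sd,panelLAMP1,Hoechst,nuclei,morphology,20
nuclei_perimeter_mean,panelLAMP1,Hoechst,nuclei,morphology,34
nuclei_perimeter_sd,panelLAMP1,Hoechst,nuclei,morphology,8.5
nuclei_form_factor_mean,panelLAMP1,Hoechst,nuclei,morphology,0.85
nuclei_form_factor_sd,panelLAMP1,Hoechst,nuclei,morphology,0.2125
nuclei_compactness_mean,panelLAMP1,Hoechst,nuclei,morphology,0.8
nuclei_compactness_sd,panelLAMP1,Hoechst,nuclei,morphology,0.2
nuclei_eccentricity_mean,panelLAMP1,Hoechst,nuclei,morphology,0.55
nuclei_eccentricity_sd,panelLAMP1,Hoechst,nuclei,morphology,0.1375
all_cells_count,panelLAMP1,MAP2,all_cells,count,90
all_cells_Hoechst_int_mean,panelLAMP1,Hoechst,all_cells,intensity,1500
all_cells_Hoechst_int_median,panelLAMP1,Hoechst,all_cells,intensity,1425
all_cells_Hoechst_int_sd,panelLAMP1,Hoechst,all_cells,intensity,450
all_cells_Hoechst_int_p90,panelLAMP1,Hoechst,all_cells,intensity,2250
all_cells_aSyn_int_mean,panelLAMP1,aSyn,all_cells,intensity,800
all_cells_aSyn_int_median,panelLAMP1,aSyn,all_cells,intensity,760
all_cells_aSyn_int_sd,panelLAMP1,aSyn,all_cells,intensity,240
all_cells_aSyn_int_p90,panelLAMP1,aSyn,all_cells,intensity,1200
all_cells_LAMP1_int_mean,panelLAMP1,LAMP1,all_cells,intensity,700
all_cells_LAMP1_int_median,panelLAMP1,LAMP1,all_cells,intensity,665
all_cells_LAMP1_int_sd,panelLAMP1,LAMP1,all_cells,intensity,210
all_cells_LAMP1_int_p90,panelLAMP1,LAMP1,all_cells,intensity,1050
all_cells_MAP2_int_mean,panelLAMP1,MAP2,all_cells,intensity,1200
all_cells_MAP2_int_median,panelLAMP1,MAP2,all_cells,intensity,1140
all_cells_MAP2_int_sd,panelLAMP1,MAP2,all_cells,intensity,360
all_cells_MAP2_int_p90,panelLAMP1,MAP2,all_cells,intensity,1800
all_cells_area_mean,panelLAMP1,MAP2,all_cells,morphology,300
all_cells_area_sd,panelLAMP1,MAP2,all_cells,morphology,75
all_cells_perimeter_mean,panelLAMP1,MAP2,all_cells,morphology,75
all_cells_perimeter_sd,panelLAMP1,MAP2,all_cells,morphology,18.75
all_cells_form_factor_mean,panelLAMP1,MAP2,all_cells,morphology,0.6
all_cells_form_factor_sd,panelLAMP1,MAP2,all_cells,morphology,0.15
all_cells_compactness_mean,panelLAMP1,MAP2,all_cells,morphology,0.55
all_cells_compactness_sd,panelLAMP1,MAP2,all_cells,morphology,0.1375
all_cells_eccentricity_mean,panelLAMP1,MAP2,all_cells,morphology,0.65
all_cells_eccentricity_sd,panelLAMP1,MAP2,all_cells,morphology,0.1625
all_cells_ratio_aSyn_MAP2,panelLAMP1,aSyn,all_cells,ratio,0.666666666666667
all_cells_ratio_LAMP1_MAP2,panelLAMP1,LAMP1,all_cells,ratio,0.583333333333333
MAP2_pos_count,panelLAMP1,MAP2,MAP2_pos,count,60
MAP2_pos_fraction,panelLAMP1,MAP2,MAP2_pos,ratio,0.65
MAP2_pos_MAP2_int_mean,panelLAMP1,MAP2,MAP2_pos,intensity,1200
MAP2_pos_MAP2_int_sd,panelLAMP1,MAP2,MAP2_pos,intensity,360
MAP2_pos_aSyn_int_mean,panelLAMP1,aSyn,MAP2_pos,intensity,800
neurites_total_length,panelLAMP1,MAP2,neurites,morphology,4000
neurites_branch_points,panelLAMP1,MAP2,neurites,count,150
neurites_end_points,panelLAMP1,MAP2,neurites,count,180
neurites_branch_density,panelLAMP1,MAP2,neurites,ratio,0.0375
lyso_count,panelLAMP1,LAMP1,lysosomes,count,250
lyso_count_per_cell,panelLAMP1,LAMP1,lysosomes,count,2.8
lyso_area_total,panelLAMP1,LAMP1,lysosomes,morphology,2000
lyso_area_per_cell,panelLAMP1,LAMP1,lysosomes,morphology,22
lyso_area_mean,panelLAMP1,LAMP1,lysosomes,morphology,8
lyso_LAMP1_int_mean,panelLAMP1,LAMP1,lysosomes,intensity,700
lyso_LAMP1_int_median,panelLAMP1,LAMP1,lysosomes,intensity,665
lyso_LAMP1_int_sd,panelLAMP1,LAMP1,lysosomes,intensity,210
lyso_LAMP1_int_p90,panelLAMP1,LAMP1,lysosomes,intensity,1050
lyso_form_factor_mean,panelLAMP1,LAMP1,lysosomes,morphology,0.75
lyso_compactness_mean,panelLAMP1,LAMP1,lysosomes,morphology,0.65
lyso_eccentricity_mean,panelLAMP1,LAMP1,lysosomes,morphology,0.55
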