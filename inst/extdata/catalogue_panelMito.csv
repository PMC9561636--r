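name,panel,channel,population,family,baseline
field_Hoechst_int_mean,panelMito,Hoechst,field,intensity,1500
field_Hoechst_int_sd,panelMito,Hoechst,field,intensity,450
field_Hoechst_int_p90,panelMito,Hoechst,field,intensity,2250
field_calcein_int_mean,panelMito,calcein,field,intensity,1100
field_calcein_int_sd,panelMito,calcein,field,intensity,330
field_calcein_int_p90,panelMito,calcein,field,intensity,1650
field_TMRM_int_mean,panelMito,TMRM,field,intensity,900
field_TMRM_int_sd,panelMito,TMRM,field,intensity,270
field_TMRM_int_p90,panelMito,TMRM,field,intensity,1350
field_TMRM_gran_r2,panelMito,TMRM,field,texture,0.2
field_TMRM_gran_r4,panelMito,TMRM,field,texture,0.35
field_calcein_gran_r2,panelMito,calcein,field,texture,0.2
field_calcein_gran_r4,panelMito,calcein,field,texture,0.35
nuclei_count,panelMito,Hoechst,nuclei,count,120
nuclei_density,panelMito,Hoechst,nuclei,count,0.00325520833333333
nuclei_Hoechst_int_mean,panelMito,Hoechst,nuclei,intensity,1500
nuclei_Hoechst_int_median,panelMito,Hoechst,nuclei,intensity,1425
nuclei_Hoechst_int_sd,panelMito,Hoechst,nuclei,intensity,450
nuclei_Hoechst_int_p90,panelMito,Hoechst,nuclei,intensity,2250
nuclei_area_mean,panelMito,Hoechst,nuclei,morphology,80
nuclei_area_sd,panelMito,Hoechst,nuclei,morphology,20
nuclei_perimeter_mean,panelMito,Hoechst,nuclei,morphology,34
nuclei_perimeter_sd,panelMito,Hoechst,nuclei,morphology,8.5
nuclei_form_factor_mean,panelMito,Hoechst,nuclei,morphology,0.85
nuclei_form_factor_sd,panelMito,Hoechst,nuclei,morphology,0.2125
nuclei_compactness_mean,panelMito,Hoechst,nuclei,morphology,0.8
nuclei_compactness_sd,panelMito,Hoechst,nuclei,morphology,0.2
nuclei_eccentricity_mean,panelMito,Hoechst,nuclei,morphology,0.55
nuclei_eccentricity_sd,panelMito,Hoechst,nuclei,morphology,0.1375
all_cells_count,panelMito,calcein,all_cells,count,90
all_cells_Hoechst_int_mean,panelMito,Hoechst,all_cells,intensity,1500
all_cells_Hoechst_int_median,panelMito,Hoechst,all_cells,intensity,1425
all_cells_Hoechst_int_sd,panelMito,Hoechst,all_cells,intensity,450
all_cells_Hoechst_int_p90,panelMito,Hoechst,all_cells,intensity,2250
all_cells_calcein_int_mean,panelMito,calcein,all_cells,intensity,1100
all_cells_calcein_int_median,panelMito,calcein,all_cells,intensity,1045
all_cells_calcein_int_sd,panelMito,calcein,all_cells,intensity,330
all_cells_calcein_int_p90,panelMito,calcein,all_cells,intensity,1650
all_cells_TMRM_int_mean,panelMito,TMRM,all_cells,intensity,900
all_cells_TMRM_int_median,panelMito,TMRM,all_cells,intensity,855
all_cells_TMRM_int_sd,panelMito,TMRM,all_cells,intensity,270
all_cells_TMRM_int_p90,panelMito,TMRM,all_cells,intensity,1350
all_cells_area_mean,panelMito,calcein,all_cells,morphology,300
all_cells_area_sd,panelMito,calcein,all_cells,morphology,75
all_cells_perimeter_mean,panelMito,calcein,all_cells,morphology,75
all_cells_perimeter_sd,panelMito,calcein,all_cells,morphology,18.75
all_cells_form_factor_mean,panelMito,calcein,all_cells,morphology,0.6
all_cells_form_factor_sd,panelMito,calcein,all_cells,morphology,0.15
all_cells_compactness_mean,panelMito,calcein,all_cells,morphology,0.55
all_cells_compactness_sd,panelMito,calcein,all_cells,morphology,0.1375
all_cells_eccentricity_mean,panelMito,calcein,all_cells,morphology,0.65
all_cells_eccentricity_sd,panelMito,calcein,all_cells,morphology,0.1625
all_cells_ratio_TMRM_calcein,panelMito,TMRM,all_cells,ratio,0.818181818181818
mito_count,panelMito,TMRM,mitochondria,count,400
mito_count_per_cell,panelMito,TMRM,mitochondria,count,4.5
mito_per_nucleus,panelMito,TMRM,mitochondria,ratio,3.3
mito_area_total,panelMito,TMRM,mitochondria,morphology,4800
mito_area_frac,panelMito,TMRM,mitochondria,ratio,0.15
mito_area_per_cell,panelMito,TMRM,mitochondria,morphology,55
mito_TMRM_int_mean,panelMito,TMRM,mitochondria,intensity,900
mito_TMRM_int_median,panelMito,TMRM,mitochondria,intensity,855
mito_TMRM_int_sd,panelMito,TMRM,mitochondria,intensity,270
mito_TMRM_int_p90,panelMito,TMRM,mitochondria,intensity,1350
mito_TMRM_int_total,panelMito,TMRM,mitochondria,intensity,270000
mito_TMRM_int_cv,panelMito,TMRM,mitochondria,intensity,0.3
mito_TMRM_int_total_per_cell,panelMito,TMRM,mitochondria,intensity,49500
mito_TMRM_bg_ratio,panelMito,TMRM,mitochondria,ratio,3
mito_calcein_int_mean,panelMito,calcein,mitochondria,intensity,1100
mito_calcein_int_median,panelMito,calcein,mitochondria,intensity,1045
mito_calcein_int_sd,panelMito,calcein,mitochondria,intensity,330
mito_calcein_int_p90,panelMito,calcein,mitochondria,intensity,1650
mito_area_mean,panelMito,TMRM,mitochondria,morphology,12
mito_area_median,panelMito,TMRM,mitochondria,morphology,11.64
mito_area_sd,panelMito,TMRM,mitochondria,morphology,3
mito_perimeter_mean,panelMito,TMRM,mitochondria,morphology,13
mito_perimeter_median,panelMito,TMRM,mitochondria,morphology,12.61
mito_perimeter_sd,panelMito,TMRM,mitochondria,morphology,3.25
mito_form_factor_mean,panelMito,TMRM,mitochondria,morphology,0.7
mito_form_factor_median,panelMito,TMRM,mitochondria,morphology,0.679
mito_form_factor_sd,panelMito,TMRM,mitochondria,morphology,0.175
mito_compactness_mean,panelMito,TMRM,mitochondria,morphology,0.6
mito_compactness_median,panelMito,TMRM,mitochondria,morphology,0.582
mito_compactness_sd,panelMito,TMRM,mitochondria,morphology,0.15
mito_eccentricity_mean,panelMito,TMRM,mitochondria,morphology,0.6
mito_eccentricity_median,panelMito,TMRM,mitochondria,morphology,0.582
mito_eccentricity_sd,panelMito,TMRM,mitochondria,morphology,0.15
mito_area_p90,panelMito,TMRM,mitochondria,morphology,16.8
mito_form_factor_p10,panelMito,TMRM,mitochondria,morphology,0.42
mito_compactness_p90,panelMito,TMRM,mitochondria,morphology,0.84
mito_eccentricity_p90,panelMito,TMRM,mitochondria,morphology,0.84
mito_extent_mean,panelMito,TMRM,mitochondria,morphology,0.63
mito_aspect_ratio_mean,panelMito,TMRM,mitochondria,morphology,1.6
mito_nn_dist_mean,panelMito,TMRM,mitochondria,morphology,9
mito_extent_sd,panelMito,TMRM,mitochondria,morphology,0.1575
mito_aspect_ratio_sd,panelMito,TMRM,mitochondria,morphology,0.4
mito_nn_dist_sd,panelMito,TMRM,mitochondria,morphology,3
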