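trait	fragment	neg_log10_p	contig	start	end
max_plant_height_HP	1	5.03	chr1_1	51032941	51032981
min_plant_height_LP	2	5.22	chr3_2	75169820	75169862
min_plant_height_LP	3	5.05	chr1_1	28858224	28858255
shoot_fresh_matter_HP	2	4.28	chr8_1	83148789	83148841
shoot_fresh_matter_LP	2	5.22	chr1_2	49246587	49246623
shoot_dry_matter_LP	1	4.45	chr1_1	81146399	81146433
root_dry_matter_LP	1	5.57	chr1_4	28947995	28948032
STI_RDM	3	4.56	chr1_1	6017225	6017259
STI_RDM	5	4.17	chr1_1	46131987	46132018
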