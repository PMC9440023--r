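indicator_id,label,secondary_id,primary_id,Mj,sd,Vj,Kj,Cs,Ca,Cr
electric_scald_instrument,Electric scald instrument,high_temp_solid,induction_methods,7.80,1.80,0.23,7.80,0.790,0.873,0.832
hydrothermal_flask,Hydrothermal flask,high_temp_solid,induction_methods,5.00,2.40,0.48,5.00,0.450,0.787,0.619
water_bath_hot_steel_bar,Water bath hot steel bar,high_temp_solid,induction_methods,5.73,2.05,0.36,5.73,0.590,0.827,0.709
hot_water_bath,Hot-water bath,high_temp_liquid,induction_methods,7.33,1.62,0.22,7.33,0.770,0.900,0.835
water_spray_injury_cup,Water spray injury cup,high_temp_liquid,induction_methods,5.13,2.36,0.46,5.13,0.490,0.780,0.635
water_bath_high_temp_gauze,Water bath high temperature gauze,high_temp_liquid,induction_methods,5.27,2.14,0.41,5.27,0.550,0.780,0.665
skin_application_fuel,Skin application fuel,contact_combustion,induction_methods,4.67,2.67,0.57,4.67,0.510,0.813,0.662
infrared_heater,Infrared heater,thermal_radiation,induction_methods,4.67,2.82,0.60,4.67,0.470,0.780,0.625
back,Back,,burn_sites,9.07,1.34,0.15,9.07,0.920,0.927,0.924
abdomen,Abdomen,,burn_sites,5.00,3.18,0.64,5.00,0.520,0.813,0.667
buttock,Buttock,,burn_sites,3.93,3.04,0.77,3.93,0.400,0.747,0.574
temp_lt_80,Less than 80 C,,induction_temperature,4.93,2.86,0.58,4.93,0.640,0.853,0.747
temp_80_100,Between 80 and 100 C,,induction_temperature,8.40,1.25,0.15,8.40,0.770,0.940,0.856
temp_gt_200,More than 200 C,,induction_temperature,3.40,3.44,1.01,3.40,0.320,0.753,0.537
pentobarbital_sodium,Pentobarbital sodium,general_anesthesia,anesthesia,7.67,2.89,0.38,7.67,0.850,0.913,0.882
chloral_hydrate,Chloral hydrate,general_anesthesia,anesthesia,6.20,2.76,0.45,6.20,0.670,0.840,0.755
ketamine,Ketamine,general_anesthesia,anesthesia,4.13,2.99,0.72,4.13,0.360,0.760,0.560
isoflurane,Isoflurane,general_anesthesia,anesthesia,5.73,3.43,0.60,5.73,0.440,0.813,0.627
serazine,Serazine,general_anesthesia,anesthesia,2.87,2.03,0.71,2.87,0.230,0.713,0.472
uratan,Uratan,general_anesthesia,anesthesia,3.73,2.86,0.77,3.73,0.320,0.753,0.537
diethyl_ether,Diethyl ether,general_anesthesia,anesthesia,5.40,3.09,0.57,5.40,0.510,0.847,0.679
lidocaine,Lidocaine,local_anesthesia,anesthesia,3.87,3.56,0.92,3.87,0.450,0.767,0.609
bupivacaine,Bupivacaine,local_anesthesia,anesthesia,3.27,2.89,0.88,3.27,0.270,0.707,0.489
barium_sulfide,Barium sulfide,chemical_method,skin_preparation,4.67,2.98,0.64,4.67,0.390,0.787,0.589
sodium_sulfide,Sodium sulfide,chemical_method,skin_preparation,6.80,3.23,0.47,6.80,0.750,0.873,0.812
razor,Razor,physical_method,skin_preparation,4.73,3.84,0.81,4.73,0.490,0.780,0.635
push_shear,Push shear,physical_method,skin_preparation,6.80,3.19,0.47,6.80,0.710,0.867,0.789
rearing_temperature,Rearing temperature,rearing_environment,housing_post_surgery,8.13,2.78,0.34,8.13,0.810,0.920,0.865
rearing_humidity,Rearing humidity,rearing_environment,housing_post_surgery,8.07,2.79,0.35,8.07,0.800,0.920,0.860
environmental_ventilation,Environmental ventilation,rearing_environment,housing_post_surgery,7.87,2.78,0.35,7.87,0.790,0.900,0.845
ambient_light,Ambient light,rearing_environment,housing_post_surgery,7.20,3.06,0.42,7.20,0.730,0.907,0.819
rearing_density,Rearing density,rearing_environment,housing_post_surgery,8.07,2.74,0.34,8.07,0.800,0.913,0.857
bedding_material,Selection of bedding material,rearing_environment,housing_post_surgery,7.53,3.12,0.41,7.53,0.730,0.907,0.819
feed,Feed,rearing_food,housing_post_surgery,6.73,3.45,0.51,6.73,0.730,0.900,0.815
drinking_water,Drinking water,rearing_food,housing_post_surgery,7.13,3.32,0.47,7.13,0.770,0.907,0.839
lactate_ringers,Lactate Ringer's solution,shock_prevention,intervention_post_surgery,6.87,3.40,0.50,6.87,0.710,0.880,0.795
hyperoxia_nacl,Hyperoxia compound sodium chloride,shock_prevention,intervention_post_surgery,4.53,3.54,0.78,4.53,0.350,0.740,0.545
env_disinfection,Disinfection of animal living environment,shock_prevention,intervention_post_surgery,7.07,3.47,0.49,7.07,0.750,0.880,0.815
vaccination,Vaccination,infection_prevention,intervention_post_surgery,2.07,2.35,1.14,2.07,0.240,0.680,0.460
penicillin_cephalosporin,"Penicillin, generation I cephalosporin",infection_prevention,intervention_post_surgery,5.00,3.69,0.74,5.00,0.600,0.807,0.704
analgin,Analgin,infection_prevention,intervention_post_surgery,3.40,3.28,0.97,3.40,0.440,0.727,0.584
lappaconitine,Lappaconitine,analgesia,intervention_post_surgery,2.73,2.86,1.05,2.73,0.320,0.720,0.520
dexmedetomidine,Dexmedetomidine,analgesia,intervention_post_surgery,2.80,2.97,1.06,2.80,0.310,0.707,0.509
wound_color,Wound color,macroscopic_results,assessment_criteria,8.73,1.53,0.17,8.73,0.880,0.940,0.910
blister_formation,Blister formation,macroscopic_results,assessment_criteria,7.67,2.57,0.34,7.67,0.800,0.900,0.850
eschar_formation,Eschar formation,macroscopic_results,assessment_criteria,8.53,1.63,0.19,8.53,0.880,0.927,0.904
epidermis_injury,Epidermis injury,microscopic_results,assessment_criteria,7.53,3.05,0.41,7.53,0.870,0.940,0.905
dermal_injury,Dermal injury,microscopic_results,assessment_criteria,8.13,2.31,0.28,8.13,0.840,0.927,0.884
subcutaneous_injury,Subcutaneous injury,microscopic_results,assessment_criteria,8.67,1.74,0.20,8.67,0.870,0.927,0.899
success_rate,Success rate of model construction,other_comments,assessment_criteria,8.47,1.54,0.18,8.47,0.830,0.927,0.879
time_consumption,Model construction time consumption,other_comments,assessment_criteria,7.33,2.36,0.32,7.33,0.840,0.920,0.880
resource_consumption,Model building resource consumption,other_comments,assessment_criteria,6.87,2.70,0.39,6.87,0.760,0.880,0.820
rat_mortality,Mortality of rats,other_comments,assessment_criteria,8.07,1.95,0.24,8.07,0.790,0.907,0.849
complication_incidence,Incidence of complications,other_comments,assessment_criteria,7.93,2.24,0.28,7.93,0.750,0.893,0.822
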