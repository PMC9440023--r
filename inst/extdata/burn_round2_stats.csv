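indicator_id,label,secondary_id,primary_id,Mj,sd,Vj,Kj,Cs,Ca,Cr
electric_scald_instrument,Electric scald instrument,high_temp_solid,induction_methods,8.08,1.00,0.12,7.69,0.720,0.753,0.737
hydrothermal_flask,Hydrothermal flask,high_temp_solid,induction_methods,6.38,1.86,0.29,7.69,0.600,0.720,0.660
water_bath_hot_steel_bar,Water bath hot steel bar,high_temp_solid,induction_methods,5.77,1.89,0.33,7.69,0.560,0.693,0.627
hot_water_bath,Hot-water bath,high_temp_liquid,induction_methods,7.38,1.44,0.20,7.69,0.680,0.760,0.720
water_spray_injury_cup,Water spray injury cup,high_temp_liquid,induction_methods,5.38,1.69,0.31,0,0.480,0.653,0.567
water_bath_high_temp_gauze,Water bath high temperature gauze,high_temp_liquid,induction_methods,5.54,1.87,0.34,7.69,0.600,0.707,0.654
skin_application_fuel,Skin application fuel,contact_combustion,induction_methods,5.15,1.99,0.39,7.69,0.493,0.667,0.580
infrared_heater,Infrared heater,thermal_radiation,induction_methods,4.85,2.41,0.50,0,0.453,0.680,0.567
ionizing_radiation,Ionizing radiation,thermal_radiation,induction_methods,4.15,2.54,0.61,7.69,0.400,0.660,0.530
back,Back,,burn_sites,9.15,0.77,0.08,38.46,0.800,0.767,0.784
abdomen,Abdomen,,burn_sites,5.08,2.92,0.57,15.38,0.533,0.640,0.587
buttock,Buttock,,burn_sites,5.92,2.59,0.44,15.38,0.5467,0.660,0.603
temp_lt_80,Less than 80 C,,induction_temperature,8.62,0.84,0.10,15.38,0.707,0.773,0.740
temp_80_100,Between 80 and 100 C,,induction_temperature,4.85,2.32,0.48,0,0.573,0.667,0.620
pentobarbital_sodium,Pentobarbital sodium,general_anesthesia,anesthesia,8.00,2.63,0.33,23.08,0.733,0.733,0.733
chloral_hydrate,Chloral hydrate,general_anesthesia,anesthesia,7.38,2.02,0.27,23.08,0.733,0.793,0.763
isoflurane,Isoflurane,general_anesthesia,anesthesia,5.23,2.97,0.57,0,0.387,0.640,0.514
diethyl_ether,Diethyl ether,general_anesthesia,anesthesia,5.46,2.44,0.45,0,0.533,0.667,0.600
uratan,Uratan,general_anesthesia,anesthesia,4.23,2.52,0.59,0,0.360,0.633,0.497
serazine,Serazine,general_anesthesia,anesthesia,3.08,1.98,0.64,0,0.320,0.593,0.457
barium_sulfide,Barium sulfide,chemical_method,skin_preparation,7.69,2.05,0.27,38.46,0.667,0.740,0.704
sodium_sulfide,Sodium sulfide,chemical_method,skin_preparation,6.08,2.53,0.42,7.69,0.427,0.687,0.557
razor,Razor,physical_method,skin_preparation,7.08,2.56,0.36,23.08,0.653,0.713,0.683
push_shear,Push shear,physical_method,skin_preparation,6.15,2.57,0.42,15.38,0.573,0.700,0.637
rearing_temperature,Rearing temperature,rearing_environment,housing_post_surgery,8.08,2.53,0.31,30.77,0.653,0.727,0.690
rearing_humidity,Rearing humidity,rearing_environment,housing_post_surgery,8.00,2.48,0.31,30.77,0.707,0.720,0.714
environmental_ventilation,Environmental ventilation,rearing_environment,housing_post_surgery,7.85,2.48,0.32,30.77,0.680,0.707,0.694
rearing_density,Rearing density,rearing_environment,housing_post_surgery,7.46,2.62,0.35,23.08,0.680,0.720,0.700
bedding_material,Selection of bedding material,rearing_environment,housing_post_surgery,7.85,2.44,0.31,23.08,0.627,0.713,0.670
ambient_light,Ambient light,rearing_environment,housing_post_surgery,7.54,2.44,0.32,23.08,0.613,0.693,0.653
feed,Feed,rearing_food,housing_post_surgery,7.46,2.93,0.39,30.77,0.667,0.720,0.694
drinking_water,Drinking water,rearing_food,housing_post_surgery,7.46,2.93,0.39,30.77,0.667,0.713,0.690
lactate_ringers,Lactate Ringer's solution,shock_prevention,intervention_post_surgery,7.62,2.56,0.34,23.08,0.667,0.693,0.680
hyperoxia_nacl,Hyperoxia compound sodium chloride,shock_prevention,intervention_post_surgery,5.85,2.35,0.40,0,0.533,0.647,0.590
env_disinfection,Disinfection of animal living environment,infection_prevention,intervention_post_surgery,7.08,2.70,0.38,23.08,0.640,0.687,0.664
penicillin_cephalosporin,"Penicillin, generation I cephalosporin",infection_prevention,intervention_post_surgery,4.62,2.50,0.54,0,0.547,0.633,0.590
wound_color,Wound was pale,macroscopic_results,assessment_criteria,8.85,1.10,0.12,38.46,0.747,0.780,0.764
eschar_formation,Eschar formation,macroscopic_results,assessment_criteria,8.77,0.89,0.10,23.08,0.760,0.773,0.767
blister_formation,Blister formation,macroscopic_results,assessment_criteria,7.46,2.71,0.36,23.08,0.693,0.760,0.727
subcutaneous_injury,Subcutaneous injury,microscopic_results,assessment_criteria,9.15,0.77,0.08,28.46,0.760,0.787,0.774
dermal_injury,Dermal injury,microscopic_results,assessment_criteria,8.85,0.95,0.11,23.08,0.760,0.773,0.767
epidermis_injury,Epidermis injury,microscopic_results,assessment_criteria,8.85,0.86,0.10,23.08,0.773,0.787,0.780
success_rate,Success rate of model construction,other_comments,assessment_criteria,8.69,0.82,0.09,15.38,0.733,0.773,0.753
complication_incidence,Incidence of complications,other_comments,assessment_criteria,8.23,1.37,0.17,15.38,0.720,0.747,0.734
rat_mortality,Mortality of rats,other_comments,assessment_criteria,8.31,1.07,0.13,15.38,0.733,0.753,0.743
resource_consumption,Model building resource consumption,other_comments,assessment_criteria,7.08,2.13,0.30,15.38,0.653,0.740,0.697
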