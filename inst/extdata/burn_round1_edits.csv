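round,action,indicator_id,label,tier,parent_id,note
1,delete,local_anesthesia,Local anesthesia,2,anesthesia,secondary indicator removed after expert discussion
1,delete,analgesia,Analgesia,2,intervention_post_surgery,secondary indicator removed after expert discussion
1,delete,temp_gt_200,More than 200 C,3,induction_temperature,removed by boundary-value screen and discussion
1,delete,ketamine,Ketamine,3,general_anesthesia,removed by boundary-value screen and discussion
1,delete,lidocaine,Lidocaine,3,local_anesthesia,parent secondary indicator removed
1,delete,bupivacaine,Bupivacaine,3,local_anesthesia,parent secondary indicator removed
1,delete,vaccination,Vaccination,3,infection_prevention,removed by boundary-value screen and discussion
1,delete,analgin,Analgin,3,infection_prevention,removed by boundary-value screen and discussion
1,delete,lappaconitine,Lappaconitine,3,analgesia,parent secondary indicator removed
1,delete,dexmedetomidine,Dexmedetomidine,3,analgesia,parent secondary indicator removed
1,delete,time_consumption,Model construction time consumption,3,other_comments,removed on expert advice; subsumed by resource consumption
1,add,ionizing_radiation,Ionizing radiation,3,thermal_radiation,new induction method proposed by experts
1,rename,wound_color,Wound was pale,3,macroscopic_results,macroscopic criterion reworded by experts
1,move,env_disinfection,Disinfection of animal living environment,3,infection_prevention,reclassified from shock prevention to infection prevention
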