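# Resting-state network definitions over the 78-region cortical registry.
# The registry defaults to the package's shipped 78 AAL cortical labels; an
# explicit "registry:" list here overrides it. Memberships are editable
# data: alternative network definitions are alternative files.
networks:
  DMN:
    - Frontal_Sup_Medial_L
    - Frontal_Sup_Medial_R
    - Frontal_Med_Orb_L
    - Frontal_Med_Orb_R
    - Cingulum_Ant_L
    - Cingulum_Ant_R
    - Cingulum_Post_L
    - Cingulum_Post_R
    - Precuneus_L
    - Precuneus_R
    - Parietal_Inf_L
    - Parietal_Inf_R
    - Angular_L
    - Angular_R
    - ParaHippocampal_L
    - ParaHippocampal_R
  FPN_left:
    - Frontal_Sup_L
    - Frontal_Mid_L
    - Frontal_Inf_Tri_L
    - Parietal_Sup_L
    - Parietal_Inf_L
    - SupraMarginal_L
    - Angular_L
  FPN_right:
    - Frontal_Sup_R
    - Frontal_Mid_R
    - Frontal_Inf_Tri_R
    - Parietal_Sup_R
    - Parietal_Inf_R
    - SupraMarginal_R
    - Angular_R
  ECN:
    - Frontal_Sup_L
    - Frontal_Sup_R
    - Frontal_Mid_L
    - Frontal_Mid_R
    - Cingulum_Ant_L
    - Cingulum_Ant_R
    - Cingulum_Mid_L
    - Cingulum_Mid_R
    - Supp_Motor_Area_L
    - Supp_Motor_Area_R
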