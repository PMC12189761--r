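# Default hierarchical partition of the AAL-116 atlas:
# level 1 = eight anatomical sets, level 2 = hemisphere subsets
# (CV is midline and passes through), level 3 = atlas leaves.
# The per-hemisphere leaf counts {TL:10, FL:4, PFC:12, PL:8, OL:6, SC:5, CB:9}
# and CV:8 are enforced at construction; the region-to-set assignment is an
# editable convention.
TL:
  TL.L:
    - Hippocampus.L
    - ParaHippocampal.L
    - Amygdala.L
    - Fusiform.L
    - Heschl.L
    - Temporal_Sup.L
    - Temporal_Pole_Sup.L
    - Temporal_Mid.L
    - Temporal_Pole_Mid.L
    - Temporal_Inf.L
  TL.R:
    - Hippocampus.R
    - ParaHippocampal.R
    - Amygdala.R
    - Fusiform.R
    - Heschl.R
    - Temporal_Sup.R
    - Temporal_Pole_Sup.R
    - Temporal_Mid.R
    - Temporal_Pole_Mid.R
    - Temporal_Inf.R
FL:
  FL.L:
    - Precentral.L
    - Rolandic_Oper.L
    - Supp_Motor_Area.L
    - Paracentral_Lobule.L
  FL.R:
    - Precentral.R
    - Rolandic_Oper.R
    - Supp_Motor_Area.R
    - Paracentral_Lobule.R
PFC:
  PFC.L:
    - Frontal_Sup.L
    - Frontal_Sup_Orb.L
    - Frontal_Mid.L
    - Frontal_Mid_Orb.L
    - Frontal_Inf_Oper.L
    - Frontal_Inf_Tri.L
    - Frontal_Inf_Orb.L
    - Olfactory.L
    - Frontal_Sup_Medial.L
    - Frontal_Med_Orb.L
    - Rectus.L
    - Cingulum_Ant.L
  PFC.R:
    - Frontal_Sup.R
    - Frontal_Sup_Orb.R
    - Frontal_Mid.R
    - Frontal_Mid_Orb.R
    - Frontal_Inf_Oper.R
    - Frontal_Inf_Tri.R
    - Frontal_Inf_Orb.R
    - Olfactory.R
    - Frontal_Sup_Medial.R
    - Frontal_Med_Orb.R
    - Rectus.R
    - Cingulum_Ant.R
PL:
  PL.L:
    - Cingulum_Mid.L
    - Cingulum_Post.L
    - Postcentral.L
    - Parietal_Sup.L
    - Parietal_Inf.L
    - SupraMarginal.L
    - Angular.L
    - Precuneus.L
  PL.R:
    - Cingulum_Mid.R
    - Cingulum_Post.R
    - Postcentral.R
    - Parietal_Sup.R
    - Parietal_Inf.R
    - SupraMarginal.R
    - Angular.R
    - Precuneus.R
OL:
  OL.L:
    - Calcarine.L
    - Cuneus.L
    - Lingual.L
    - Occipital_Sup.L
    - Occipital_Mid.L
    - Occipital_Inf.L
  OL.R:
    - Calcarine.R
    - Cuneus.R
    - Lingual.R
    - Occipital_Sup.R
    - Occipital_Mid.R
    - Occipital_Inf.R
SC:
  SC.L:
    - Insula.L
    - Caudate.L
    - Putamen.L
    - Pallidum.L
    - Thalamus.L
  SC.R:
    - Insula.R
    - Caudate.R
    - Putamen.R
    - Pallidum.R
    - Thalamus.R
CB:
  CB.L:
    - Cerebelum_Crus1.L
    - Cerebelum_Crus2.L
    - Cerebelum_3.L
    - Cerebelum_4_5.L
    - Cerebelum_6.L
    - Cerebelum_7b.L
    - Cerebelum_8.L
    - Cerebelum_9.L
    - Cerebelum_10.L
  CB.R:
    - Cerebelum_Crus1.R
    - Cerebelum_Crus2.R
    - Cerebelum_3.R
    - Cerebelum_4_5.R
    - Cerebelum_6.R
    - Cerebelum_7b.R
    - Cerebelum_8.R
    - Cerebelum_9.R
    - Cerebelum_10.R
CV:
  CV.mid:
    - Vermis_1_2
    - Vermis_3
    - Vermis_4_5
    - Vermis_6
    - Vermis_7
    - Vermis_8
    - Vermis_9
    - Vermis_10
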