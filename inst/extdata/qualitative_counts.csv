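region,structure_id,measure,event,judgment,numerator,denominator
ISB,c5_root,accuracy,,,13,15
ISB,c5_root,fp,,,1,15
ISB,c5_root,fn,,,1,15
ISB,c6_root,accuracy,,,15,15
ISB,c6_root,fp,,,0,15
ISB,c6_root,fn,,,0,15
AxB,axillary_artery,accuracy,,,15,15
AxB,axillary_artery,fp,,,0,15
AxB,axillary_artery,fn,,,0,15
AxB,median_nerve,accuracy,,,13,15
AxB,median_nerve,fp,,,2,15
AxB,median_nerve,fn,,,0,15
AxB,musculocutaneous_nerve,accuracy,,,12,15
AxB,musculocutaneous_nerve,fp,,,0,15
AxB,musculocutaneous_nerve,fn,,,3,15
AxB,radial_nerve,accuracy,,,11,13
AxB,radial_nerve,fp,,,2,13
AxB,radial_nerve,fn,,,0,13
AxB,ulnar_nerve,accuracy,,,14,15
AxB,ulnar_nerve,fp,,,1,15
AxB,ulnar_nerve,fn,,,0,15
ESPB,transverse_process,accuracy,,,12,15
ESPB,transverse_process,fp,,,0,15
ESPB,transverse_process,fn,,,3,15
ESPB,pleura,accuracy,,,14,15
ESPB,pleura,fp,,,0,15
ESPB,pleura,fn,,,1,15
RSB,rectus_sheath,accuracy,,,15,15
RSB,rectus_sheath,fp,,,0,15
RSB,rectus_sheath,fn,,,0,15
RSB,peritoneum,accuracy,,,15,15
RSB,peritoneum,fp,,,0,15
RSB,peritoneum,fn,,,0,15
ACB,femoral_artery,accuracy,,,15,15
ACB,femoral_artery,fp,,,0,15
ACB,femoral_artery,fn,,,0,15
ACB,saphenous_nerve,accuracy,,,14,15
ACB,saphenous_nerve,fp,,,0,15
ACB,saphenous_nerve,fn,,,1,15
SNB,sciatic_nerve,accuracy,,,15,15
SNB,sciatic_nerve,fp,,,0,15
SNB,sciatic_nerve,fn,,,0,15
ISB,c5_root,risk,nerve_trauma,increase,2,15
ISB,c5_root,risk,nerve_trauma,no_change,0,15
ISB,c5_root,risk,nerve_trauma,decrease,13,15
ISB,c6_root,risk,nerve_trauma,increase,1,15
ISB,c6_root,risk,nerve_trauma,no_change,3,15
ISB,c6_root,risk,nerve_trauma,decrease,11,15
AxB,axillary_artery,risk,nerve_trauma,increase,0,15
AxB,axillary_artery,risk,nerve_trauma,no_change,0,15
AxB,axillary_artery,risk,nerve_trauma,decrease,15,15
AxB,median_nerve,risk,nerve_trauma,increase,1,15
AxB,median_nerve,risk,nerve_trauma,no_change,3,15
AxB,median_nerve,risk,nerve_trauma,decrease,11,15
AxB,musculocutaneous_nerve,risk,nerve_trauma,increase,1,15
AxB,musculocutaneous_nerve,risk,nerve_trauma,no_change,4,15
AxB,musculocutaneous_nerve,risk,nerve_trauma,decrease,10,15
AxB,radial_nerve,risk,nerve_trauma,increase,1,13
AxB,radial_nerve,risk,nerve_trauma,no_change,1,13
AxB,radial_nerve,risk,nerve_trauma,decrease,11,13
AxB,ulnar_nerve,risk,nerve_trauma,increase,1,15
AxB,ulnar_nerve,risk,nerve_trauma,no_change,1,15
AxB,ulnar_nerve,risk,nerve_trauma,decrease,13,15
ESPB,transverse_process,risk,pneumothorax_pleura,increase,1,15
ESPB,transverse_process,risk,pneumothorax_pleura,no_change,4,15
ESPB,transverse_process,risk,pneumothorax_pleura,decrease,10,15
ESPB,pleura,risk,pneumothorax_pleura,increase,2,15
ESPB,pleura,risk,pneumothorax_pleura,no_change,2,15
ESPB,pleura,risk,pneumothorax_pleura,decrease,11,15
RSB,rectus_sheath,risk,peritoneal_violation,increase,0,15
RSB,rectus_sheath,risk,peritoneal_violation,no_change,2,15
RSB,rectus_sheath,risk,peritoneal_violation,decrease,13,15
RSB,peritoneum,risk,peritoneal_violation,increase,0,15
RSB,peritoneum,risk,peritoneal_violation,no_change,3,15
RSB,peritoneum,risk,peritoneal_violation,decrease,12,15
ACB,femoral_artery,risk,nerve_trauma,increase,0,15
ACB,femoral_artery,risk,nerve_trauma,no_change,0,15
ACB,femoral_artery,risk,nerve_trauma,decrease,15,15
ACB,saphenous_nerve,risk,nerve_trauma,increase,1,15
ACB,saphenous_nerve,risk,nerve_trauma,no_change,2,15
ACB,saphenous_nerve,risk,nerve_trauma,decrease,12,15
SNB,sciatic_nerve,risk,nerve_trauma,increase,0,15
SNB,sciatic_nerve,risk,nerve_trauma,no_change,2,15
SNB,sciatic_nerve,risk,nerve_trauma,decrease,13,15
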