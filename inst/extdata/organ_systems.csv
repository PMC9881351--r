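tissue,system
spinal_cord,Nervous
motor_cortex,Nervous
cerebellum,Nervous
whole_blood,Haematologic/immune
bone_marrow,Haematologic/immune
thymus,Haematologic/immune
liver,Digestive
small_intestine,Digestive
colon,Digestive
lung,Respiratory
trachea,Respiratory
heart,Circulatory
skeletal_muscle,Circulatory
placenta,Placenta
thyroid,Endocrine
adrenal_gland,Endocrine
testis,Genital
ovary,Genital
skin,Others
kidney,Others
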