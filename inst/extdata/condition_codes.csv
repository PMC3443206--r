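code,label,group,symptom_exempt,treatment_rule_applies
cancer,Cancer (incl. lymphoid and haematopoietic),cancer,FALSE,TRUE
myocardial_infarction,Myocardial infarction,cardiovascular,FALSE,TRUE
angina,Angina pectoris,cardiovascular,FALSE,TRUE
stroke,Stroke,cardiovascular,FALSE,TRUE
heart_failure,Heart failure,cardiovascular,FALSE,TRUE
lower_limb_arterial_disease,Lower limb arterial occlusive disease,cardiovascular,FALSE,TRUE
venous_insufficiency,Venous insufficiency,cardiovascular,FALSE,TRUE
hypertension,High blood pressure,cardiovascular,FALSE,TRUE
psoriasis,Psoriasis,dermatological,FALSE,TRUE
eczema,Eczema,dermatological,FALSE,TRUE
slough,Slough,dermatological,FALSE,TRUE
ulcer,Ulcer,digestive,FALSE,TRUE
cirrhosis,Cirrhosis and other liver diseases,digestive,FALSE,TRUE
food_allergy,Food allergies,digestive,FALSE,TRUE
diabetes,Diabetes mellitus,endocrine,FALSE,TRUE
thyroid_disorder,Disorders of the thyroid gland,endocrine,FALSE,TRUE
obesity,Obesity (BMI >= 30; derived from height and weight),endocrine,TRUE,FALSE
back_pain,Back pain,musculoskeletal,TRUE,FALSE
neck_pain,Neck pain,musculoskeletal,TRUE,FALSE
scoliosis,Scoliosis,musculoskeletal,FALSE,TRUE
rheumatoid_arthritis,Rheumatoid arthritis,musculoskeletal,FALSE,TRUE
other_inflammatory_arthritis,Other inflammatory arthritis,musculoskeletal,FALSE,TRUE
knee_hip_osteoarthritis,Knee and hip osteoarthritis,musculoskeletal,FALSE,TRUE
other_osteoarthritis,Other osteoarthritis,musculoskeletal,FALSE,TRUE
osteoporosis,Osteoporosis,musculoskeletal,FALSE,TRUE
headache,Headache,neurological,TRUE,FALSE
epilepsy,Epilepsy,neurological,FALSE,TRUE
dementia,Dementia,neurological,FALSE,TRUE
parkinson,Parkinson's disease,neurological,FALSE,TRUE
multiple_sclerosis,Multiple sclerosis,neurological,FALSE,TRUE
other_neurological,Other unspecified neurological problems,neurological,FALSE,TRUE
depression,Depression,psychiatric,FALSE,TRUE
anxiety,Anxiety,psychiatric,FALSE,TRUE
autism,Autism,psychiatric,FALSE,TRUE
schizophrenia,Schizophrenia,psychiatric,FALSE,TRUE
trisomy_21,Trisomy 21,psychiatric,FALSE,TRUE
other_psychiatric,Other unspecified psychiatric impairments,psychiatric,FALSE,TRUE
asthma,Asthma,respiratory,FALSE,TRUE
chronic_bronchitis,Chronic bronchitis,respiratory,FALSE,TRUE
hay_fever,Hay fever,respiratory,FALSE,TRUE
eyesight_problem,Eyesight problems (incl. cataract strabismus glaucoma),sensorial,TRUE,FALSE
hearing_loss,Hearing loss or hearing aid,sensorial,TRUE,FALSE
sequelae_of_injury,Sequelae of injury,sequelae_of_injury,FALSE,TRUE
urinary_incontinence,Urinary incontinence,urological,FALSE,TRUE
urinary_tract_infection,Infection of the urinary tract,urological,FALSE,TRUE
lithiasis,Lithiasis,urological,FALSE,TRUE
prostate_adenoma,Prostate adenoma,urological,FALSE,TRUE
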