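subject_id,age_months,breed,sex,trainability,stranger_directed_aggression,owner_directed_aggression,dog_directed_aggression,familiar_dog_aggression,chasing,stranger_directed_fear,nonsocial_fear,separation_related_problems,touch_sensitivity,excitability,attachment_attention_seeking,energy
pat01,64,Jack Russell terrier,FC,1.50,0.80,0.00,2.63,0.50,3.50,1.50,1.83,0.00,0.50,2.00,1.67,2.00
pat02,66,Belgian shepherd,MC,2.25,0.00,0.63,2.88,1.00,3.50,0.00,0.17,0.00,0.75,2.83,0.17,2.00
pat03,71,Galgo Espanol,FC,1.75,0.00,0.38,0.00,2.50,1.75,4.00,3.83,0.13,0.25,1.17,3.00,1.00
pat04,64,White Swiss Shepherd,FC,3.50,3.20,0.00,2.50,0.00,2.50,0.75,0.67,0.88,0.50,1.67,3.17,2.00
pat05,111,Akita Inu,MC,2.88,1.00,0.25,1.25,ND,2.25,1.50,0.00,0.00,1.50,1.00,2.00,0.00
pat06,90,Labrador retriever,MC,1.50,0.00,0.00,0.75,ND,1.00,3.00,2.83,0.00,0.50,2.00,0.33,0.00
pat07,41,Spanish water dog,MC,3.63,2.30,0.00,1.00,ND,1.50,0.00,0.50,0.50,1.00,2.33,2.67,0.00
pat08,86,Galgo Espanol,MC,0.13,0.00,0.00,4.00,0.00,1.25,3.75,3.83,0.00,0.50,1.67,0.17,1.00
pat09,55,Belgian shepherd,FC,3.75,0.70,0.00,0.13,ND,1.00,1.50,2.67,0.00,1.00,2.33,3.67,4.00
pat10,98,Border collie,MC,2.13,0.00,0.00,1.00,ND,2.00,0.50,2.00,0.13,1.00,2.67,1.67,1.50
pat11,57,American hairless terrier,FC,3.75,0.00,0.00,0.75,0.50,2.25,1.75,2.67,0.00,1.25,2.00,3.67,2.00
pat12,151,Jack Russell terrier,MC,1.38,0.30,0.25,2.50,0.00,0.25,1.25,0.67,1.88,3.25,2.67,3.00,2.00
pat13,39,English cocker spaniel,FC,2.63,2.00,0.00,2.50,0.50,2.75,3.00,1.00,0.25,1.75,2.33,2.17,2.00
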