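# 19 breast-cancer risk features named relevant by domain experts
rs146875699
rs2279744
rs190372148
rs71310379
rs137902538
rs202004587
rs149633775
Age
NSAIDs
Offspring
Contraceptives
Socioeconomic level
BMI
Smoker
Total energy
Family history of BC
Total Met in 10 years
Ethyl alcohol
Age of menarche
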