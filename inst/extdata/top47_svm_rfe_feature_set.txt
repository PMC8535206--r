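# Top-47 features of the aggregated SVM-RFE ranking (rank order)
Age
Legumes
RS-201340741
RS-141143854
Family history of BC
RS-201100551
RS-148728256
RS-146208471
RS-148214998
Iron
RS-71310379
RS-143582231
RS-34154613
RS-4645959
Digestible sugars
Folic acid
RS-78419579
RS-144811392
RS-5746105
Dairy
Potassium
RS-146848959
Fish
RS-2758331
Vitamin C
Vegetables
RS-2287498
Total energy
Carotenoids
Edible
Fruits
RS-202004587
Flavonoids
NSAIDs
RS-138607522
Abdominal obesity
Ethyl alcohol
RS-145519500
Stilbenes
RS-2279744
Animal protein
Oral contraceptives
RS-141363120
Magnesium
Smoker (ever)
Lignans
Retinoids
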