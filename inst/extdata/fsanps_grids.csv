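component,role,threshold,points
energy_kj,unfavorable,335,1
energy_kj,unfavorable,670,2
energy_kj,unfavorable,1005,3
energy_kj,unfavorable,1340,4
energy_kj,unfavorable,1675,5
energy_kj,unfavorable,2010,6
energy_kj,unfavorable,2345,7
energy_kj,unfavorable,2680,8
energy_kj,unfavorable,3015,9
energy_kj,unfavorable,3350,10
sugar_g,unfavorable,4.5,1
sugar_g,unfavorable,9,2
sugar_g,unfavorable,13.5,3
sugar_g,unfavorable,18,4
sugar_g,unfavorable,22.5,5
sugar_g,unfavorable,27,6
sugar_g,unfavorable,31,7
sugar_g,unfavorable,36,8
sugar_g,unfavorable,40,9
sugar_g,unfavorable,45,10
satfat_g,unfavorable,1,1
satfat_g,unfavorable,2,2
satfat_g,unfavorable,3,3
satfat_g,unfavorable,4,4
satfat_g,unfavorable,5,5
satfat_g,unfavorable,6,6
satfat_g,unfavorable,7,7
satfat_g,unfavorable,8,8
satfat_g,unfavorable,9,9
satfat_g,unfavorable,10,10
sodium_mg,unfavorable,90,1
sodium_mg,unfavorable,180,2
sodium_mg,unfavorable,270,3
sodium_mg,unfavorable,360,4
sodium_mg,unfavorable,450,5
sodium_mg,unfavorable,540,6
sodium_mg,unfavorable,630,7
sodium_mg,unfavorable,720,8
sodium_mg,unfavorable,810,9
sodium_mg,unfavorable,900,10
fiber_g,favorable,0.7,1
fiber_g,favorable,1.4,2
fiber_g,favorable,2.1,3
fiber_g,favorable,2.8,4
fiber_g,favorable,3.5,5
protein_g,favorable,1.6,1
protein_g,favorable,3.2,2
protein_g,favorable,4.8,3
protein_g,favorable,6.4,4
protein_g,favorable,8,5
fruitveg_pct,favorable,40,1
fruitveg_pct,favorable,60,2
fruitveg_pct,favorable,80,5
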