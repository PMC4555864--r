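species,mass_kg,c_vol_m3,c_vol_sub_m3,alpha_vol_m3
Bison bison,558.5,1.573,0.473,0.555
Bos taurus,323.7,0.666,0.219,0.277
Camelus dromedarius,427.0,1.436,0.332,0.434
Cervus elaphus,89.5,0.435,0.084,0.114
Dicerorhinus sumatrensis,470.3,1.062,0.363,0.466
Elephas maximus,2352.0,5.107,2.093,2.287
Equus caballus,517.5,1.525,0.370,0.467
Giraffa camelopardalis,638.2,2.479,0.447,0.612
Loxodonta africana,2734.9,7.005,2.748,3.330
Megaloceros giganteus,435.6,1.199,0.301,0.361
Rangifer tarandus,95.8,0.394,0.076,0.123
Sus scrofa,107.4,0.257,0.079,0.108
Tapirus indicus,295.3,0.530,0.172,0.230
Ursus maritimus,206.1,0.367,0.111,0.159
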