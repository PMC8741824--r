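field,light,background,weed_density_per_m2,transect_length_m,fov_width_m
HEN1,day,"Canola stubble, red-orange soil",3.1,50,1
HEN2,day,"Heavy wheat stubble, red soil",9.3,50,1
WAG1,day,"Lupin stubble, red-orange soil",18.7,50,1
WAG2,day,"Grazed barley stubble",3.3,50,1
COB1,day,"Dark brown soil, freshly tilled",9.8,50,1
NIGHT1,night,"Canola stubble",9.6,50,1
NIGHT2,night,"Dark brown soil, freshly tilled",7.8,50,1
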