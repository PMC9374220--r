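Id,Shore,N,HE,PSize,EO
GA2,North,12,0.65,75,BC
GA3,North,31,0.72,2000,A
GA4,North,7,0.63,250,B
GA5,North,15,0.62,2000,AB
LA1,North,11,0.701,50,BC
LO1,North,21,0.754,50,B
MD1,North,18,0.724,100,B
SM1,North,56,0.771,250,AB
BE1,South,24,0.634,100,B
DC1,South,17,0.736,50,AB
MA1,South,9,0.68,20,BC
MA2,South,10,0.625,30,AB
MA3,South,25,0.75,25,AB
MI1,South,20,0.73,500,AB
MI2,South,20,0.71,30,BC
MI3,South,6,0.74,100,B
SF1,South,6,0.74,25,AB
SF3,South,6,0.61,6,C
SF4,South,13,0.73,25,BC
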