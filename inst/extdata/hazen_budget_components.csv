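species,year,compartment,load,se,units
water,2015,snow_on_lake,0.069,0.015,km3
water,2015,snow_from_land,0.055,0.012,km3
water,2015,glacial_rivers,0.948,NA,km3
water,2015,total_inputs,1.07,0.027,km3
water,2015,outflow,1.07,0.027,km3
water,2016,snow_on_lake,0.060,0.008,km3
water,2016,snow_from_land,0.059,0.089,km3
water,2016,glacial_rivers,0.281,NA,km3
water,2016,total_inputs,0.400,0.097,km3
water,2016,outflow,0.400,0.097,km3
NH4,2015,snow_on_lake,0.584,0.115,t
NH4,2015,snow_from_land,1.67,0.454,t
NH4,2015,glacial_rivers,22.9,15.9,t
NH4,2015,total_inputs,25.2,16.5,t
NH4,2015,outflow,3.79,1.38,t
NH4,2016,snow_on_lake,0.551,0.092,t
NH4,2016,snow_from_land,1.48,0.371,t
NH4,2016,glacial_rivers,5.42,2.15,t
NH4,2016,total_inputs,7.45,2.61,t
NH4,2016,outflow,1.13,0.411,t
NO3NO2,2015,snow_on_lake,2.81,0.611,t
NO3NO2,2015,snow_from_land,5.63,1.89,t
NO3NO2,2015,glacial_rivers,35.1,4.84,t
NO3NO2,2015,total_inputs,43.6,7.34,t
NO3NO2,2015,outflow,12.0,7.59,t
NO3NO2,2016,snow_on_lake,2.22,0.361,t
NO3NO2,2016,snow_from_land,4.98,1.59,t
NO3NO2,2016,glacial_rivers,12.0,1.34,t
NO3NO2,2016,total_inputs,19.2,3.29,t
NO3NO2,2016,outflow,3.57,2.26,t
SO4,2015,snow_on_lake,73.0,0.016,t
SO4,2015,snow_from_land,993,235,t
SO4,2015,glacial_rivers,13400,2420,t
SO4,2015,total_inputs,14420,2661,t
SO4,2015,outflow,9400,1440,t
SO4,2016,snow_on_lake,77.8,0.016,t
SO4,2016,snow_from_land,879,188,t
SO4,2016,glacial_rivers,3580,411,t
SO4,2016,total_inputs,4540,599,t
SO4,2016,outflow,2790,428,t
TDP,2015,snow_on_lake,0.177,0.037,t
TDP,2015,snow_from_land,1.00,0.309,t
TDP,2016,snow_on_lake,0.134,0.029,t
TDP,2016,snow_from_land,1.08,0.282,t
dSiO2,2015,snow_on_lake,5.88,0.001,t
dSiO2,2015,snow_from_land,16.0,3.21,t
dSiO2,2015,glacial_rivers,181,59.2,t
dSiO2,2015,total_inputs,203,62.4,t
dSiO2,2015,outflow,246,75.8,t
dSiO2,2016,snow_on_lake,5.09,0.001,t
dSiO2,2016,snow_from_land,14.2,2.44,t
dSiO2,2016,glacial_rivers,56.9,11.0,t
dSiO2,2016,total_inputs,76.2,13.5,t
dSiO2,2016,outflow,73.2,22.5,t
DIC,2015,snow_on_lake,139,0.028,t
DIC,2015,snow_from_land,102,21.0,t
DIC,2015,glacial_rivers,6310,474,t
DIC,2015,total_inputs,6550,495,t
DIC,2015,outflow,9700,2470,t
DIC,2016,snow_on_lake,117,0.019,t
DIC,2016,snow_from_land,88.0,15.4,t
DIC,2016,glacial_rivers,1920,117,t
DIC,2016,total_inputs,2120,132,t
DIC,2016,outflow,2880,735,t
DOC,2015,snow_on_lake,6.92,0.002,t
DOC,2015,snow_from_land,0.087,0.023,t
DOC,2015,glacial_rivers,364,59.6,t
DOC,2015,total_inputs,371,59.6,t
DOC,2015,outflow,203,55.9,t
DOC,2016,snow_on_lake,13.3,0.003,t
DOC,2016,snow_from_land,0.077,0.018,t
DOC,2016,glacial_rivers,109,14.5,t
DOC,2016,total_inputs,123,14.6,t
DOC,2016,outflow,60.6,16.6,t
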