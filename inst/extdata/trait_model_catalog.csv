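set,experiment,selector,stage,trait,vi,slope,intercept,r2,rmse,rrmse_pct
rcm_comparison,Test1,EL,,LAI,CIgreen,0.2138,2.1213,0.6159,1.1894,24.43
rcm_comparison,Test1,SEL,,LAI,CIgreen,0.3392,1.2471,0.7714,0.9175,18.84
rcm_comparison,Test1,PEL,,LAI,CIgreen,0.3360,1.0176,0.8364,0.7772,15.96
rcm_comparison,Test1,EL,,AGB,CIgreen,31.8780,58.2600,0.6283,258.5627,47.60
rcm_comparison,Test1,SEL,,AGB,CIgreen,38.2660,46.7340,0.5478,267.8949,49.32
rcm_comparison,Test1,PEL,,AGB,CIgreen,39.6540,3.7036,0.6534,255.5819,47.05
rcm_comparison,Test1,EL,,CCC,CIgreen,8.7479,96.1880,0.5419,56.6725,27.16
rcm_comparison,Test1,SEL,,CCC,CIgreen,14.7750,50.8720,0.7689,40.2487,19.29
rcm_comparison,Test1,PEL,,CCC,CIgreen,14.3360,44.2940,0.8001,37.4370,17.94
rcm_comparison,Test2,EL,,LAI,CIgreen,0.2944,0.6926,0.8350,0.8195,18.38
rcm_comparison,Test2,SEL,,LAI,CIgreen,0.3210,0.6811,0.8026,0.8755,19.63
rcm_comparison,Test2,PEL,,LAI,CIgreen,0.3390,0.4682,0.8533,0.7820,17.53
rcm_comparison,Test2,EL,,AGB,CIgreen,42.1860,30.6610,0.4654,271.4445,48.08
rcm_comparison,Test2,SEL,,AGB,CIgreen,45.0950,31.0940,0.4403,277.7335,49.20
rcm_comparison,Test2,PEL,,AGB,CIgreen,47.5830,4.9777,0.4690,270.5139,47.92
rcm_comparison,Test2,EL,,CCC,CIgreen,11.9540,28.8210,0.8588,30.9864,17.05
rcm_comparison,Test2,SEL,,CCC,CIgreen,13.2190,26.1690,0.8492,31.5024,17.33
rcm_comparison,Test2,PEL,,CCC,CIgreen,13.9210,17.8800,0.8975,27.5072,15.13
altitude_comparison,Test1,100,,LAI,CIgreen,0.3360,1.0176,0.8364,0.7762,15.94
altitude_comparison,Test1,150,,LAI,CIgreen,0.3539,0.9984,0.8546,0.7318,15.03
altitude_comparison,Test1,200,,LAI,CIgreen,0.3421,0.9721,0.8317,0.7874,16.17
altitude_comparison,Test1,250,,LAI,CIgreen,0.3554,0.8772,0.8411,0.7649,15.71
altitude_comparison,Test1,100,,AGB,CIgreen,39.6540,3.7036,0.6534,162.6172,36.55
altitude_comparison,Test1,150,,AGB,CIgreen,43.5090,-4.7125,0.6363,165.2271,36.81
altitude_comparison,Test1,200,,AGB,CIgreen,38.6880,6.2879,0.6133,171.7673,38.60
altitude_comparison,Test1,250,,AGB,CIgreen,40.1870,1.6108,0.6130,171.8381,38.62
altitude_comparison,Test1,100,,CCC,CIgreen,14.3360,44.2940,0.8001,37.4370,17.94
altitude_comparison,Test1,150,,CCC,CIgreen,14.6560,48.3090,0.8103,35.0322,17.07
altitude_comparison,Test1,200,,CCC,CIgreen,15.0250,37.4670,0.8430,33.1784,15.90
altitude_comparison,Test1,250,,CCC,CIgreen,15.5450,34.0210,0.8455,32.9088,15.77
altitude_comparison,Test2,50,,LAI,CIgreen,0.2788,0.8889,0.7761,1.1150,25.00
altitude_comparison,Test2,100,,LAI,CIgreen,0.3390,0.4682,0.8533,0.7820,17.53
altitude_comparison,Test2,50,,AGB,CIgreen,39.5530,55.1480,0.4301,280.2471,49.64
altitude_comparison,Test2,100,,AGB,CIgreen,47.5830,4.9777,0.4690,270.5139,47.92
altitude_comparison,Test2,50,,CCC,CIgreen,11.4960,34.5720,0.8228,33.9458,18.67
altitude_comparison,Test2,100,,CCC,CIgreen,13.9210,17.8800,0.8975,27.5072,15.13
yield_stage,Test2,50,booting,Yield,EVI2,3186.2660,-2002.0312,0.3859,124.7462,15.4756
yield_stage,Test2,100,booting,Yield,EVI2,5475.6664,-3455.1211,0.5177,110.5548,13.7151
yield_stage,Test2,50,heading,Yield,WDRVI,1337.1689,-120.3483,0.3165,131.6050,16.3265
yield_stage,Test2,100,heading,Yield,WDRVI,2867.1955,-1007.9788,0.5170,110.6357,13.7251
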