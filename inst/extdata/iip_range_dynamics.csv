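species,CurPR,F126PR,F585PR,M126PR,M585PR,F126RRI,F585RRI,M126RRI,M585RRI,F126RSI,F585RSI,M126RSI,M585RSI
Linepithema humile,7.16,8.76,10.92,8.87,10.41,1.19,1.47,1.20,1.40,0.79,0.63,0.78,0.66
Anoplophora glabripennis,4.23,9.74,16.11,11.20,12.00,2.32,3.83,2.66,2.85,0.49,0.36,0.43,0.47
Aedes albopictus,11.66,22.00,27.11,21.74,26.63,1.84,2.26,1.82,2.23,0.66,0.55,0.67,0.57
Pheidole megacephala,8.23,13.46,20.51,15.78,18.09,1.58,2.39,1.86,2.12,0.71,0.52,0.64,0.54
Anopheles quadrimaculatus,3.98,6.72,7.20,5.85,6.53,1.64,1.77,1.42,1.60,0.65,0.64,0.66,0.67
Vespula vulgaris,7.09,10.46,11.42,8.24,9.93,1.41,1.51,1.11,1.33,0.78,0.62,0.86,0.71
Anoplolepis gracilipes,5.84,8.12,9.57,9.01,9.14,1.41,1.67,1.57,1.59,0.75,0.69,0.73,0.69
Cinara cupressi,17.25,19.83,34.63,24.19,30.44,1.13,1.98,1.38,1.74,0.80,0.53,0.66,0.61
Platydemus manokwari,3.86,3.56,8.33,4.52,3.62,0.95,2.22,1.20,0.96,0.60,0.48,0.58,0.50
Coptotermes formosanus,1.19,2.14,6.47,1.45,3.59,1.72,5.25,1.17,2.92,0.56,0.29,0.58,0.39
Lymantria dispar,8.76,11.81,21.23,11.26,18.77,1.36,2.44,1.29,2.16,0.81,0.52,0.83,0.58
Trogoderma granarium,12.91,18.20,23.22,25.21,41.04,1.39,1.76,1.93,3.13,0.71,0.54,0.65,0.47
Wasmannia auropunctata,8.86,12.00,18.58,13.68,18.11,1.32,2.05,1.51,2.00,0.74,0.58,0.72,0.60
Solenopsis invicta,4.78,8.15,10.17,7.63,7.40,1.66,2.07,1.55,1.50,0.60,0.47,0.57,0.52
Bemisia tabaci,10.45,11.90,12.57,17.41,14.29,1.14,1.21,1.67,1.37,0.78,0.75,0.71,0.75
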