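trait,P-1498_C,P-1498_D,P-1319_C,P-1319_D,DKC-6581_C,DKC-6581_D,DKC-6697_C,DKC-6697_D,N61X-3110_C,N61X-3110_D,N59B-311A_C,N59B-311A_D
PH,38.75,24.5,36.25,22.25,37.5,22,36.75,19.25,38.75,23,35.75,21.25
LA,2600.07,600.93,2033.23,563.28,2353.26,582.54,2339.89,564.03,2128.37,569.95,1787.6,601.94
LN,6.5,5.25,6.5,5,6.75,5.25,6.25,4.75,6.5,5,6.25,4.75
SPAD,39.6,32.85,38.55,30.48,43.33,34.6,36.3,30.15,41.83,35.93,39.58,33.1
LRL,59.25,66.75,56,65,58.25,62.25,55.75,61.5,57.5,62,55.75,61
RN,14.25,11.75,14,11,17.25,10.75,16.75,10,16,10.75,15.75,11.5
LDW,7.63,2.17,6.66,2.06,7.91,2.29,7.22,2.09,6.42,2.28,5.2,2.17
SDW,3.75,1.63,3.57,1.39,5,1.43,4.62,1.33,4.18,1.4,3.2,1.33
SHDW,11.39,3.8,10.63,3.45,12.91,3.73,11.83,3.42,10.59,3.65,8.4,3.5
RDW,1.15,1.38,1.09,1.29,1.29,1.21,1.22,1.15,1.22,1.14,0.94,1.13
RSR,0.1,0.38,0.1,0.37,0.11,0.36,0.11,0.34,0.11,0.35,0.11,0.32
TDW,12.1,4.88,11.71,4.74,14.2,4.93,13.24,4.57,11.81,4.49,9.33,4.63
RSA,705.54,663.65,945.96,811.77,1116.13,742.54,1105.68,716.5,983.6,810.23,916.94,740.31
RD,0.37,0.47,0.43,0.49,0.46,0.49,0.52,0.49,0.46,0.5,0.47,0.47
TRL,6025.57,4507.91,7041.5,5220.65,7748.8,4791.84,6752.4,4613.85,6693.33,5202.8,6531.25,5037.82
RV,6.66,7.78,10.15,10.06,12.99,9.16,14.46,8.95,11.61,10.12,10.48,8.67
NRT,38899.25,21485.75,40179.75,23325.75,42571.75,28464.25,32207.25,23252.5,33353,23283.75,41103.75,25777.25
NRF,49278.5,37754.75,64806,47135.5,79550.25,42397.25,73482.25,38932.25,69277.75,48596.25,65371.5,47962.25
NRC,4905,2871,5707.75,3363.25,6115.75,2803.75,5467,2728,5630.75,3143,5127.25,3469
Phot,35.83,16.2,30.48,15.75,42.13,18.2,36.98,15.25,42.78,15.88,40.9,15.03
FvFm,0.49,0.3,0.45,0.29,0.42,0.36,0.42,0.32,0.48,0.35,0.47,0.3
ETR,197.27,85.24,191.75,77.42,236.78,109.17,225.14,108.06,210.93,103.98,208.56,92.21
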