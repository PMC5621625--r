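indicator,sex,key,L,M,S
hfa,male,0,1,49,0.035
hfa,male,3,1,54.3,0.035
hfa,male,6,1,59.4,0.035
hfa,male,9,1,64.31,0.035
hfa,male,12,1,69.02,0.035
hfa,male,15,1,73.53,0.035
hfa,male,18,1,77.84,0.035
hfa,male,21,1,81.95,0.035
hfa,male,24,1,85.86,0.035
hfa,male,27,1,89.58,0.035
hfa,male,30,1,93.1,0.035
hfa,male,33,1,96.42,0.035
hfa,male,36,1,99.54,0.035
hfa,male,39,1,102.47,0.035
hfa,male,42,1,105.2,0.035
hfa,male,45,1,107.72,0.035
hfa,male,48,1,110.06,0.035
hfa,male,51,1,112.19,0.035
hfa,male,54,1,114.12,0.035
hfa,male,57,1,115.86,0.035
hfa,male,60,1,117.4,0.035
hfa,male,63,1,118.74,0.035
hfa,male,66,1,119.88,0.035
hfa,male,69,1,120.83,0.035
hfa,male,72,1,121.58,0.035
hfa,female,0,1,48.02,0.036
hfa,female,3,1,53.21,0.036
hfa,female,6,1,58.22,0.036
hfa,female,9,1,63.02,0.036
hfa,female,12,1,67.64,0.036
hfa,female,15,1,72.05,0.036
hfa,female,18,1,76.28,0.036
hfa,female,21,1,80.31,0.036
hfa,female,24,1,84.15,0.036
hfa,female,27,1,87.79,0.036
hfa,female,30,1,91.24,0.036
hfa,female,33,1,94.49,0.036
hfa,female,36,1,97.55,0.036
hfa,female,39,1,100.42,0.036
hfa,female,42,1,103.09,0.036
hfa,female,45,1,105.57,0.036
hfa,female,48,1,107.85,0.036
hfa,female,51,1,109.95,0.036
hfa,female,54,1,111.84,0.036
hfa,female,57,1,113.54,0.036
hfa,female,60,1,115.05,0.036
hfa,female,63,1,116.37,0.036
hfa,female,66,1,117.49,0.036
hfa,female,69,1,118.41,0.036
hfa,female,72,1,119.14,0.036
wfh,male,45,-0.35,4.24,0.09
wfh,male,50,-0.35,5,0.09
wfh,male,55,-0.35,5.84,0.09
wfh,male,60,-0.35,6.76,0.09
wfh,male,65,-0.35,7.76,0.09
wfh,male,70,-0.35,8.84,0.09
wfh,male,75,-0.35,10,0.09
wfh,male,80,-0.35,11.24,0.09
wfh,male,85,-0.35,12.56,0.09
wfh,male,90,-0.35,13.96,0.09
wfh,male,95,-0.35,15.44,0.09
wfh,male,100,-0.35,17,0.09
wfh,male,105,-0.35,18.64,0.09
wfh,male,110,-0.35,20.36,0.09
wfh,male,115,-0.35,22.16,0.09
wfh,male,120,-0.35,24.04,0.09
wfh,male,125,-0.35,26,0.09
wfh,male,130,-0.35,28.04,0.09
wfh,female,45,-0.35,4.113,0.092
wfh,female,50,-0.35,4.85,0.092
wfh,female,55,-0.35,5.665,0.092
wfh,female,60,-0.35,6.557,0.092
wfh,female,65,-0.35,7.527,0.092
wfh,female,70,-0.35,8.575,0.092
wfh,female,75,-0.35,9.7,0.092
wfh,female,80,-0.35,10.903,0.092
wfh,female,85,-0.35,12.183,0.092
wfh,female,90,-0.35,13.541,0.092
wfh,female,95,-0.35,14.977,0.092
wfh,female,100,-0.35,16.49,0.092
wfh,female,105,-0.35,18.081,0.092
wfh,female,110,-0.35,19.749,0.092
wfh,female,115,-0.35,21.495,0.092
wfh,female,120,-0.35,23.319,0.092
wfh,female,125,-0.35,25.22,0.092
wfh,female,130,-0.35,27.199,0.092
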