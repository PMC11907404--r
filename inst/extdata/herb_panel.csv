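herb,form,element,total,sd_total,dialyzable,sd_dialyzable,nondialyzable,sd_nondialyzable,sum_printed,sd_sum_printed,agreement_printed,sd_agreement_printed
basil,fresh,Cr,0.83,0.02,0.06,0.00,0.83,0.02,0.89,0.07,107,9
basil,lyophilizate,Cr,1.23,0.08,0.26,0.02,1.10,0.07,1.36,0.03,111,8
basil,dried,Cr,2.20,0.03,0.10,0.01,1.80,0.08,1.90,0.06,86.5,3.8
basil,supplement,Cr,3.52,0.26,0.09,0.01,3.16,0.30,3.25,0.22,92.3,7.3
peppermint,fresh,Cr,0.26,0.01,0.06,0.00,0.21,0.01,0.27,0.01,103,3
peppermint,lyophilizate,Cr,0.70,0.05,0.13,0.01,0.63,0.09,0.75,0.06,108,14
peppermint,dried,Cr,0.67,0.06,0.06,0.00,0.58,0.07,0.64,0.05,96.1,6.5
peppermint,supplement,Cr,1.31,0.01,0.05,0.00,1.13,0.11,1.18,0.08,90.7,6.2
rosemary,fresh,Cr,0.28,0.01,0.07,0.01,0.20,0.01,0.27,0.01,96.9,8.9
rosemary,lyophilizate,Cr,0.73,0.06,0.19,0.02,0.54,0.03,0.73,0.01,100,8
rosemary,dried,Cr,2.76,0.03,NA,NA,1.68,0.09,NA,NA,NA,NA
rosemary,supplement,Cr,0.77,0.05,0.04,0.00,0.75,0.05,0.79,0.05,103,11
basil,fresh,Mn,46.7,0.8,12.8,0.9,34.7,2.0,47.5,2.3,102,6
basil,lyophilizate,Mn,345,15,70.6,2.8,250,24,320,26,92.8,4.8
basil,dried,Mn,139,3,28.5,1.9,103,3,132,1,94.9,2.1
basil,supplement,Mn,53.3,1.9,4.24,0.22,45.1,0.4,49.3,0.6,92.6,4.4
peppermint,fresh,Mn,15.7,0.2,4.32,0.13,11.5,0.8,15.9,1.1,101,6
peppermint,lyophilizate,Mn,105,1,24.4,1.5,73.9,5.2,98.3,5.5,93.7,5.2
peppermint,dried,Mn,42.4,0.6,4.59,0.09,31.9,1.0,36.5,0.7,85.0,2.2
peppermint,supplement,Mn,132,4,9.62,0.24,107,1,117,1,88.6,2.4
rosemary,fresh,Mn,15.3,0.2,3.86,0.06,11.1,0.6,15.0,0.4,98.4,0.8
rosemary,lyophilizate,Mn,81.4,0.3,20.6,1.0,49.1,4.0,69.8,4.7,85.8,5.9
rosemary,dried,Mn,38.1,1.3,6.79,0.36,25.6,0.8,32.4,0.3,85.3,2.5
rosemary,supplement,Mn,24.5,0.7,3.25,0.09,18.4,0.4,21.7,0.3,88.4,3.7
basil,fresh,Fe,33.6,0.8,0.31,0.01,29.6,1.5,29.9,1.0,89.0,4.6
basil,lyophilizate,Fe,319,19,2.22,0.12,292,8,294,8,92.2,3.2
basil,dried,Fe,769,13,0.76,0.01,679,32,680,9,88.4,2.6
basil,supplement,Fe,1187,55,1.49,0.05,1152,42,1154,42,97.3,4.6
peppermint,fresh,Fe,44.9,0.7,0.11,0.02,45.0,4.2,45.1,4.2,100,8
peppermint,lyophilizate,Fe,257,6,1.43,0.11,285,13,287,9,112,2
peppermint,dried,Fe,222,8,0.27,0.02,192,11,192,8,86.6,5.8
peppermint,supplement,Fe,449,1,0.28,0.01,404,2,404,1,90.0,0.4
rosemary,fresh,Fe,128,3,0.77,0.01,108,2,109,1,85.0,3.1
rosemary,lyophilizate,Fe,636,7,3.03,0.04,605,19,608,14,95.5,1.4
rosemary,dried,Fe,897,57,0.16,0.01,760,25,761,18,85.1,7.0
rosemary,supplement,Fe,352,6,0.14,0.01,332,7,333,5,94.6,2.6
basil,fresh,Cu,2.04,0.06,0.32,0.01,1.83,0.15,2.15,0.15,106,8
basil,lyophilizate,Cu,12.7,0.3,1.81,0.05,10.6,0.6,12.4,0.5,98.2,3.2
basil,dried,Cu,8.63,0.16,2.21,0.10,6.53,0.38,8.75,0.38,101,5
basil,supplement,Cu,16.9,0.7,0.42,0.01,14.9,0.3,15.4,0.3,91.1,5.4
peppermint,fresh,Cu,2.11,0.09,0.38,0.01,1.68,0.15,2.07,0.15,97.9,9.4
peppermint,lyophilizate,Cu,9.68,0.07,1.37,0.15,8.92,0.27,10.3,0.1,106,1
peppermint,dried,Cu,4.91,0.16,0.63,0.04,3.73,0.12,4.36,0.06,89.0,2.1
peppermint,supplement,Cu,10.7,0.4,0.28,0.02,8.92,0.13,9.20,0.07,86.0,2.7
rosemary,fresh,Cu,0.65,0.03,0.32,0.01,0.38,0.02,0.70,0.02,109,7
rosemary,lyophilizate,Cu,2.18,0.01,1.07,0.01,1.28,0.13,2.35,0.09,108,4
rosemary,dried,Cu,6.66,0.42,0.80,0.02,5.14,0.11,5.94,0.06,89.2,4.9
rosemary,supplement,Cu,5.59,0.17,0.81,0.02,4.40,0.14,5.21,0.12,93.3,4.1
basil,fresh,Zn,11.4,0.8,0.46,0.07,10.0,0.6,10.5,0.5,91.8,0.1
basil,lyophilizate,Zn,91.6,4.7,9.83,0.60,74.4,1.6,84.2,1.6,92.0,5.1
basil,dried,Zn,19.1,0.5,5.32,0.33,12.4,0.2,17.8,0.1,93.2,3.0
basil,supplement,Zn,40.7,0.7,1.03,0.04,37.5,0.8,38.5,0.8,94.6,2.9
peppermint,fresh,Zn,10.0,0.7,2.13,0.03,6.55,0.21,8.68,0.25,87.3,6.5
peppermint,lyophilizate,Zn,42.2,1.6,10.7,0.7,35.9,0.6,46.6,0.9,110,5
peppermint,dried,Zn,30.3,0.6,5.59,0.37,21.2,1.0,26.8,0.9,88.3,2.0
peppermint,supplement,Zn,45.4,1.4,1.41,0.14,39.2,3.2,40.6,2.4,89.4,4.3
rosemary,fresh,Zn,12.4,1.1,1.87,0.10,10.8,0.7,12.6,0.6,103,13
rosemary,lyophilizate,Zn,43.8,0.2,5.34,0.64,36.1,2.5,41.4,2.9,94.7,6.8
rosemary,dried,Zn,24.6,0.5,2.87,0.13,19.2,0.9,22.1,0.8,89.8,1.8
rosemary,supplement,Zn,17.4,0.5,2.13,0.08,14.6,0.2,16.7,0.1,95.9,2.6
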