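trait,model,aic,add,dom,aa,ad,dd,residual,h2,H2
Ht1,PBLUP-A,5788.85,309.09,NA,NA,NA,NA,1469.49,0.17,NA
Ht1,PBLUP-AD,5786.88,269.57,501.60,NA,NA,NA,1009.78,0.15,0.43
Ht1,GBLUP-A,5793.20,328.42,NA,NA,NA,NA,1458.70,0.18,NA
Ht1,GBLUP-AD,5795.20,328.42,0,NA,NA,NA,1458.70,0.18,0.18
Ht1,GBLUP-ADE,5801.07,299.03,0,138.34,0,0,1359.88,0.17,0.24
Ht2,PBLUP-A,6875.41,3828.13,NA,NA,NA,NA,5818.22,0.39,NA
Ht2,PBLUP-AD,6876.84,3719.17,847.19,NA,NA,NA,5068.48,0.39,0.47
Ht2,GBLUP-A,6890.86,2999.85,NA,NA,NA,NA,6443.27,0.32,NA
Ht2,GBLUP-AD,6892.76,2963.10,135.05,NA,NA,NA,6343.47,0.31,0.33
Ht2,GBLUP-ADE,6895.17,2166.02,0.56,3573.72,0.01,0.01,3936.31,0.22,0.59
DBH1,PBLUP-A,4998.46,148.85,NA,NA,NA,NA,456.93,0.25,NA
DBH1,PBLUP-AD,5000.46,148.85,0,NA,NA,NA,456.93,0.25,0.25
DBH1,GBLUP-A,5007.54,132.64,NA,NA,NA,NA,471.71,0.22,NA
DBH1,GBLUP-AD,5009.55,132.64,0,NA,NA,NA,471.71,0.22,0.22
DBH1,GBLUP-ADE,5015.53,129.79,0,13.76,0,0,461.83,0.21,0.24
DBH2,PBLUP-A,5216.79,161.69,NA,NA,NA,NA,625.69,0.21,NA
DBH2,PBLUP-AD,5217.50,152.87,115.72,NA,NA,NA,519.30,0.19,0.34
DBH2,GBLUP-A,5219.67,158.20,NA,NA,NA,NA,627.20,0.20,NA
DBH2,GBLUP-AD,5221.43,151.11,28.06,NA,NA,NA,606.24,0.19,0.23
DBH2,GBLUP-ADE,5225.99,107.21,7.22,239.73,0,0,449.86,0.13,0.44
MFA,PBLUP-A,2541.56,4.88,NA,NA,NA,NA,11.44,0.30,NA
MFA,PBLUP-AD,2541.56,4.88,0,NA,NA,NA,11.44,0.30,0.30
MFA,GBLUP-A,2547.74,5.47,NA,NA,NA,NA,11.06,0.33,NA
MFA,GBLUP-AD,2549.74,5.47,0,NA,NA,NA,11.06,0.33,0.33
MFA,GBLUP-ADE,2555.74,5.47,0,0,0,0,11.06,0.33,0.33
MOEs,PBLUP-A,1377.57,1.31,NA,NA,NA,NA,1.81,0.42,NA
MOEs,PBLUP-AD,1379.57,1.31,0,NA,NA,NA,1.81,0.42,0.42
MOEs,GBLUP-A,1383.02,1.34,NA,NA,NA,NA,1.78,0.43,NA
MOEs,GBLUP-AD,1385.02,1.34,0,NA,NA,NA,1.78,0.43,0.43
MOEs,GBLUP-ADE,1391.02,1.34,0,0,0,0,1.78,0.43,0.43
DEN,PBLUP-A,5233.81,407.20,NA,NA,NA,NA,497.16,0.45,NA
DEN,GBLUP-A,5232.72,376.82,NA,NA,NA,NA,506.02,0.43,NA
DEN,GBLUP-AD,5234.72,376.81,0,NA,NA,NA,506.03,0.43,0.43
DEN,GBLUP-ADE,5239.82,341.84,0,176.33,0,0,378.78,0.38,0.58
MOEd,PBLUP-A,932.29,0.81,NA,NA,NA,NA,0.86,0.48,NA
MOEd,PBLUP-AD,934.29,0.81,0,NA,NA,NA,0.86,0.48,0.48
MOEd,GBLUP-A,946.17,0.68,NA,NA,NA,NA,0.96,0.42,NA
MOEd,GBLUP-AD,948.17,0.68,0,NA,NA,NA,0.96,0.42,0.42
MOEd,GBLUP-ADE,951.17,0.54,0,0.58,0,0,0.56,0.32,0.67
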