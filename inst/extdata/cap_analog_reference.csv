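analog,label,kd_nM,kd_sd_nM,capping_pct,capping_sd_pct,decapped_30min,decapped_30min_sd,expr_jaws2,expr_jaws2_sd,expr_a549,expr_a549_sd
ref_cap0,m7GpppApG,35.5,1.7,88,NA,0.90,0.04,NA,NA,NA,NA
ref_cap1,m7GpppAmpG,42.1,0.7,90,NA,0.80,0.14,1,0.43,1,0.49
ref_m6Am,m7Gpppm6AmpG,46.4,0.6,75,NA,0.67,0.02,NA,NA,NA,NA
ARCA,m27.3-OGpppG,NA,NA,NA,NA,NA,NA,0.26,0.19,0.55,0.15
bS-ARCA_D1,m27.2-OGppSpG_Rp,NA,NA,NA,NA,NA,NA,1.36,0.21,0.79,0.22
1,m7GppSpApG_Rp,12.6,0.8,86,7,0.81,0.16,0.81,0.09,0.73,0.25
2,m7GppSpApG_Sp,15.9,0.9,87,4,0.31,0.09,0.65,0.27,0.28,0.05
3,m7GppSpAmpG_Rp,14.0,0.8,88,8,0.82,0.09,1.16,0.21,1.17,0.02
4,m7GppSpAmpG_Sp,16.6,1.1,93,3,0.32,0.10,1.26,0.23,1.08,0.11
5,m7GppSpm6AmpG_Rp,17.6,0.8,59,14,0.62,0.07,1.13,0.43,1.10,0.08
6,m7GppSpm6AmpG_Sp,21.7,0.6,61,11,0.15,0.10,1.20,0.19,1.09,0.15
7,m7Gppp5SApG,31.4,1.9,80,2,0.60,0.15,0.46,0.24,0.64,0.09
8,m7Gppp5SAmpG,48.7,1.2,85,5,0.64,0.11,1.32,0.16,1.18,0.22
9,m7GppCH2pAmpG,NA,NA,88,NA,NA,NA,0.63,0.17,0.68,0.20
10,m7GppppApG,5.9,0.2,86,2,0.65,0.09,0.04,0.01,0.10,0.03
11,m7GppppAmpG,7.2,0.3,86,2,0.87,0.05,0.02,0.01,0.11,0.02
12,m7Gppppm6AmpG,7.3,0.3,65,15,0.40,0.11,0.04,0.01,0.06,0.01
13,m7GppCCl2ppApG,6.8,0.2,89,5,0.03,0.02,0.13,0.05,0.26,0.02
14,m7GppCCl2ppAmpG,9.1,0.5,90,4,0.01,0.00,0.10,0.03,0.30,0.01
15,m7GppCCl2ppm6AmpG,10.2,0.3,74,14,0.03,0.00,0.11,0.01,0.23,0.03
16,m7GppCH2ppAmpG,12.1,0.5,84,3,0.27,0.07,0.04,0.02,0.16,0.04
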