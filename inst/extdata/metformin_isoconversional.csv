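method,alpha,Ea_kJ_mol,A_per_min,dH_kJ_mol,dG_kJ_mol,dS_J_molK,r2
KAS,0.1,103.599,9.98e8,99.018,152,-86.1,0.98
KAS,0.2,111.845,5.55e9,107.112,151,-72.08,0.99
KAS,0.3,116.806,1.54e10,111.947,151,-63.79,1
KAS,0.4,99.061,3.96e8,94.028,152,-94.53,0.97
KAS,0.5,92.809,1.08e8,87.63,152,-105.56,0.98
KAS,0.6,94.962,1.69e8,89.67,152,-102.02,0.97
KAS,0.7,93.937,1.37e8,88.527,152,-103.99,0.96
KAS,0.8,98.724,3.74e8,93.172,152,-95.84,0.91
FWO,0.1,106.95,1.99e9,102.368,151,-80.35,0.98
FWO,0.2,115.065,1.08e10,110.331,151,-66.56,0.99
FWO,0.3,120.013,2.98e10,115.155,151,-58.31,1
FWO,0.4,103.422,9.76e8,98.389,151,-87.02,0.97
FWO,0.5,97.739,3.01e8,92.56,152,-97.05,0.98
FWO,0.6,99.994,4.80e8,94.702,152,-93.35,0.97
FWO,0.7,99.231,4.10e8,93.821,152,-94.86,0.96
FWO,0.8,104.062,1.13e9,98.51,151,-86.65,0.92
FRIEDMAN,0.1,110.963,4.56e9,106.382,151,-73.46,0.99
FRIEDMAN,0.2,106.753,1.94e9,102.02,151,-80.81,0.99
FRIEDMAN,0.3,127.706,1.45e11,122.848,151,-45.18,0.91
FRIEDMAN,0.4,86.736,3.05e7,81.703,152,-115.84,0.97
FRIEDMAN,0.5,135.786,7.56e11,130.607,150,-31.95,0.93
FRIEDMAN,0.6,92.668,1.05e8,87.377,152,-105.99,0.93
FRIEDMAN,0.7,94.805,1.64e8,89.395,152,-102.49,0.86
FRIEDMAN,0.8,133.758,5.07e11,128.206,150,-35.89,0.64
STARINK,0.1,103.572,9.92e8,98.991,152,-86.15,0.98
STARINK,0.2,111.799,5.50e9,107.066,151,-72.15,0.99
STARINK,0.3,116.751,1.53e10,111.893,151,-63.88,1
STARINK,0.4,99.084,3.98e8,94.051,152,-94.49,0.97
STARINK,0.5,92.866,1.09e8,87.687,152,-105.46,0.98
STARINK,0.6,95.02,1.71e8,89.728,152,-101.92,0.97
STARINK,0.7,94.007,1.39e8,88.597,152,-103.87,0.96
STARINK,0.8,98.788,3.79e8,93.237,152,-95.73,0.92
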