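component,pre_mean,pre_sd,post_mean,post_sd,diff_mean,diff_sd,percent_change,p_value
SAT,308.58,165.41,272.41,160.19,-36.17,113.43,-11.72,0.17
IMAT,21.51,76.16,22.95,73.80,1.45,5.82,6.74,0.008
VAT,118.20,75.79,107.29,78.32,-10.91,43.27,-9.23,0.27
VLDM,18.30,16.32,19.38,20.45,1.09,6.52,5.96,0.65
LDM,34.89,11.07,33.30,10.53,-1.59,8.90,-4.56,0.22
NDM,62.85,19.82,62.11,20.47,-0.74,17.73,-1.17,0.63
HDM,6.01,11.25,6.03,13.06,0.03,2.89,0.50,0.77
VHDM,3.34,1.45,2.97,1.19,-0.37,0.99,-11.08,0.01
TAT,448.29,202.07,402.66,209.24,-45.64,146.05,-10.18,0.19
TSM,125.38,28.47,123.79,29.43,-1.59,17.13,-1.27,0.38
WAIST,103.53,14.06,104.33,13.62,0.80,12.51,0.01,0.65
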