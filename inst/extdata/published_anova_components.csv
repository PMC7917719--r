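analysis,component,ss_belt,ss_residual,df_belt,df_residual,ms_belt,ms_residual,f
cwm_h,fixed,302.300,615.400,3,41,100.767,15.010,6.713
cwm_h,specific,443.900,687.000,3,41,147.967,16.756,8.831
cwm_h,intraspecific,32.620,45.650,3,41,10.873,1.113,9.766
cm_h,fixed,499.300,299.700,3,41,166.433,7.310,22.770
cm_h,specific,631.600,305.900,3,41,210.533,7.461,28.220
cm_h,intraspecific,14.580,15.670,3,41,4.860,0.382,35.130
cwm_sla,fixed,7.990,31.580,3,41,2.663,0.770,3.458
cwm_sla,specific,5.760,33.730,3,41,1.920,0.823,2.335
cwm_sla,intraspecific,11.650,3.670,3,41,3.883,0.090,43.390
cm_sla,fixed,22.120,19.890,3,41,7.373,0.485,15.200
cm_sla,specific,41.030,20.850,3,41,13.677,0.509,26.890
cm_sla,intraspecific,13.979,1.124,3,41,4.660,0.027,170.000
cwm_sm,fixed,7.503,19.429,3,41,2.501,0.474,5.278
cwm_sm,specific,7.363,20.229,3,41,2.454,0.493,4.974
cwm_sm,intraspecific,2.598,1.063,3,41,0.866,0.026,33.410
cm_sm,fixed,13.063,7.459,3,41,4.354,0.182,23.930
cm_sm,specific,14.557,8.271,3,41,4.852,0.202,24.050
cm_sm,intraspecific,3.213,0.696,3,41,1.071,0.017,63.060
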