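analysis,matrix,row,turnover,intraspecific,covariation,total
cwm_h,B,belt,302.300,32.620,108.980,443.900
cwm_h,B,residual,615.400,45.650,25.950,687.000
cwm_h,B,total,917.700,78.270,134.930,1130.900
cwm_h,C,belt,0.267,0.029,0.096,0.393
cwm_h,C,residual,0.544,0.040,0.023,0.607
cwm_h,C,total,0.811,0.069,0.119,1.000
cm_h,B,belt,499.300,14.580,117.720,631.600
cm_h,B,residual,299.700,15.670,-9.470,305.900
cm_h,B,total,799.000,30.250,108.250,937.500
cm_h,C,belt,0.533,0.016,0.126,0.674
cm_h,C,residual,0.320,0.017,-0.010,0.326
cm_h,C,total,0.852,0.032,0.115,1.000
cwm_sla,B,belt,7.990,11.650,-13.880,5.760
cwm_sla,B,residual,31.580,3.670,-1.520,33.730
cwm_sla,B,total,39.570,15.320,-15.400,39.490
cwm_sla,C,belt,0.202,0.295,-0.351,0.146
cwm_sla,C,residual,0.800,0.093,-0.038,0.854
cwm_sla,C,total,1.000,0.388,-0.390,1.000
cm_sla,B,belt,22.120,13.979,4.931,41.030
cm_sla,B,residual,19.890,1.124,-0.164,20.850
cm_sla,B,total,42.010,15.103,4.767,61.880
cm_sla,C,belt,0.357,0.226,0.080,0.663
cm_sla,C,residual,0.321,0.018,-0.003,0.337
cm_sla,C,total,0.679,0.244,0.077,1.000
cwm_sm,B,belt,7.503,2.598,-2.738,7.363
cwm_sm,B,residual,19.429,1.063,-0.263,20.229
cwm_sm,B,total,26.932,3.661,-3.001,27.592
cwm_sm,C,belt,0.272,0.094,-0.099,0.267
cwm_sm,C,residual,0.704,0.039,-0.010,0.733
cwm_sm,C,total,0.976,0.133,-0.109,1.000
cm_sm,B,belt,13.063,3.213,-1.719,14.557
cm_sm,B,residual,7.459,0.696,0.116,8.271
cm_sm,B,total,20.522,3.909,-1.603,22.828
cm_sm,C,belt,0.572,0.141,-0.075,0.638
cm_sm,C,residual,0.327,0.030,0.005,0.362
cm_sm,C,total,0.899,0.171,-0.070,1.000
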