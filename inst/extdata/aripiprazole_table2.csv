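T_K,P_MPa,rho_kg_m3,y2,sd_y2,U_y2,S_gL
308,12,768.42,3.03e-06,1.5e-07,3.06e-07,0.0237
308,15,816.06,3.91e-06,2.6e-07,5.26e-07,0.0325
308,18,848.87,4.67e-06,2.2e-07,4.50e-07,0.0404
308,21,874.40,5.13e-06,3.4e-07,6.88e-07,0.0457
308,24,895.54,5.69e-06,5.0e-07,1.007e-06,0.0520
308,27,913.69,6.34e-06,6.4e-07,1.287e-06,0.0591
308,30,929.68,6.79e-06,7.9e-07,1.586e-06,0.0644
318,12,659.73,2.62e-06,1.2e-07,2.46e-07,0.0176
318,15,743.17,3.57e-06,2.3e-07,4.66e-07,0.0270
318,18,790.18,4.71e-06,3.1e-07,6.27e-07,0.0379
318,21,823.70,5.73e-06,5.0e-07,1.007e-06,0.0481
318,24,850.10,6.75e-06,7.9e-07,1.586e-06,0.0585
318,27,872.04,7.41e-06,7.2e-07,1.448e-06,0.0659
318,30,890.92,8.01e-06,9.0e-07,1.807e-06,0.0727
328,12,506.85,2.31e-06,7.0e-08,1.48e-07,0.0119
328,15,654.94,3.04e-06,2.1e-07,4.25e-07,0.0203
328,18,724.13,4.96e-06,2.5e-07,5.10e-07,0.0366
328,21,768.74,6.43e-06,4.8e-07,9.69e-07,0.0504
328,24,801.92,7.59e-06,7.3e-07,1.468e-06,0.0620
328,27,828.51,8.47e-06,8.6e-07,1.729e-06,0.0716
328,30,850.83,9.13e-06,7.7e-07,1.551e-06,0.0792
338,12,384.17,1.83e-06,6.0e-08,1.26e-07,0.0072
338,15,555.23,2.58e-06,1.7e-07,3.44e-07,0.0146
338,18,651.18,4.99e-06,4.3e-07,8.66e-07,0.0331
338,21,709.69,6.99e-06,5.6e-07,1.129e-06,0.0506
338,24,751.17,8.77e-06,7.8e-07,1.570e-06,0.0671
338,27,783.29,9.58e-06,9.5e-07,1.910e-06,0.0764
338,30,809.58,1.036e-05,1.20e-06,2.409e-06,0.0855
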