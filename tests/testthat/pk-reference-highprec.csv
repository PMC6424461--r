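G,h,k,m,p_k
1.0725e8,8,1e40,500,0.0021070396541134287
1.0725e8,8,1e40,1000,0.42616384566599139
1.0725e8,8,1e40,2000,1.0000000000000000
1.0725e8,8,1e40,3000,1.0000000000000000
1.0725e8,8,1e40,5000,1.0000000000000000
1.0725e8,2,2e9,500,0.042453922482801668
1.0725e8,2,2e9,1000,0.15944997446131498
1.0725e8,2,2e9,2000,0.50099367125678713
1.0725e8,2,2e9,3000,0.79076627436347076
1.0725e8,2,2e9,5000,0.98703867821030376
1.0725e8,3,9e14,500,0.086658801787392564
1.0725e8,3,9e14,1000,0.51680994096269095
1.0725e8,3,9e14,2000,0.99705435001118867
1.0725e8,3,9e14,3000,0.99999999715336963
1.0725e8,3,9e14,5000,1.0000000000000000
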