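index,source,df,ss,f_printed
delta_hi,A,1,3253.7438,880.7547
delta_hi,B,3,141.8665,12.8006
delta_hi,AB,3,7.2588,0.655
delta_hi,error,358,1322.5479,NA
delta_vsi,A,1,0.8393,10.8574
delta_vsi,B,3,0.9951,4.2909
delta_vsi,AB,3,0.02893,0.1248
delta_vsi,error,358,27.6752,NA
delta_br_lf,A,1,12466.0695,187.8874
delta_br_lf,B,3,1321.992,6.6416
delta_br_lf,AB,3,296.1205,1.4877
delta_br_lf,error,358,23752.8062,NA
delta_br_hf,A,1,12432.8258,96.8926
delta_br_hf,B,3,3472.8871,9.0217
delta_br_hf,AB,3,69.3075,0.18
delta_br_hf,error,358,45936.9429,NA
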