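sample,I0,beta,tau,sse,rmse,r2
SW2015,2907,0.724,4.47,2.91e5,17.07,0.9986
SW2016,2837,0.653,4.46,2.48e5,15.76,0.9985
SW2017,3080,0.663,4.58,3.58e5,18.93,0.9983
SW2018,3434,0.796,3.08,4.23e5,20.59,0.9987
SW2019,2876,0.744,5.63,2.33e5,15.27,0.9989
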