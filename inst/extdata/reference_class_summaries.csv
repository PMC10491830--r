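index,class,n,mean,sd,range
t,1,30,1.01,1.19,5.58
t,2,30,5.87,4.40,16.44
t,3,30,14.39,10.19,38.98
t,4,30,15.17,8.36,28.64
t,5,30,29.75,13.22,51.33
t,6,30,29.97,11.68,45.35
ml,1,30,6.42,6.20,18.60
ml,2,30,7.88,8.64,41.81
ml,3,30,17.30,11.75,40.66
ml,4,30,26.79,10.59,49.60
ml,5,30,44.15,11.37,37.43
ml,6,30,48.43,8.84,33.87
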