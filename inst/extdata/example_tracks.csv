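bee_id,frame,time,x,y,orientation
1,0,0.00,100.000,50.000,0.000
1,1,0.25,100.900,50.000,5.000
2,0,0.00,115.000,50.000,180.000
2,1,0.25,114.200,50.100,176.500
3,0,0.00,200.000,120.000,90.000
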