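bee_id,partner_id,behavior,start_frame,end_frame
1,2,trophallaxis,10,49
2,1,trophallaxis,10,49
1,2,antennation,80,87
3,,sitting,0,59
3,,walking,60,99
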