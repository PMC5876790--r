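home,total,baseline_normal,baseline_abnormal,normal,warning,alert,emergency
1,61298,128,61170,43583,13886,3617,212
2,62015,26,61989,48434,12403,992,186
3,60251,247,60004,53623,6025,501,102
4,61891,105,61786,56939,4641,224,87
5,58368,67,58301,45360,11489,1318,201
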