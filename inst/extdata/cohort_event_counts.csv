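driver_id,normal_accel,aggressive_accel,dangerous_accel,normal_decel,aggressive_decel,dangerous_decel,zero
D1,1393,90,50,1108,60,56,5
D2,1827,168,150,1388,126,163,8
D3,4220,305,218,3154,279,219,6
D4,4089,183,143,3050,180,120,10
D5,497,42,25,346,42,29,2
D6,1285,39,40,972,40,30,6
D7,757,44,20,520,40,26,3
D8,1466,154,114,966,116,129,3
D9,1339,28,29,1018,30,26,6
D10,1463,102,53,1043,79,65,4
D11,907,50,81,656,56,63,5
D12,684,60,51,530,66,48,3
D13,1387,91,125,1134,93,94,6
D14,1458,70,73,1174,61,65,8
D15,3121,137,98,2787,126,94,10
D16,957,48,51,707,34,54,12
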