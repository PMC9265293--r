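driver_id,normal_speed,over_speed,dangerous_speed
D1,2094,699,0
D2,2961,831,38
D3,8470,0,0
D4,7741,143,0
D5,998,0,0
D6,849,1128,468
D7,1434,2,0
D8,2458,516,0
D9,746,1717,13
D10,2277,363,198
D11,1056,667,97
D12,1454,0,0
D14,2520,368,19
D15,6344,40,0
D16,1057,696,102
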