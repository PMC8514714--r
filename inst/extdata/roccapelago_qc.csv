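sample_id,stratum,large_target,small_target,y_target,di_published,n_typed
23-41,SU23,0.0052,0.1127,0.0875,21,25
23-1,SU23,0.0003,0.0221,0.0146,82,16
23-12,SU23,0.0051,0.0543,0.0377,11,24
23-31,SU23,0.0074,0.0226,0.0153,3,27
23-42,SU23,0.0020,0.1186,0.0905,61,21
23-46,SU23,0.0313,0.2144,0.1714,7,27
23-06,SU23,0.0064,0.0473,0.0470,7,25
23-7,SU23,0.0107,0.0344,0.0236,3,27
23-44,SU23,0.0017,0.0866,0.0819,50,24
23-27,SU23,0.0038,0.0366,0.0006,9,0
23-30,SU23,0.0037,0.0354,0.0005,9,0
23-38,SU23,0.0003,0.0159,0.0112,107,7
26-05,SU26,0.0214,0.2256,0.1753,10,27
26-32,SU26,0.0133,0.0288,0.0169,2,27
26-43,SU26,0.0021,0.0776,0.0498,37,24
26-42,SU26,0.0064,0.0261,0.0241,4,24
26-49,SU26,0.0012,0.0202,0.0143,21,14
26-1,SU26,0.0051,0.0761,0.0748,15,25
26-10,SU26,0.0041,0.0289,0.0217,7,25
26-50,SU26,0.0021,0.0115,0.0061,7,21
26-12,SU26,0.0013,0.0311,,25,0
26-24,SU26,0.0003,0.0037,0.0027,13,0
26-53,SU26,0.0023,0.0227,,9,0
28-02,SU28,,0.0151,0.0095,,10
28-05,SU28,0.0002,0.0168,0.0147,104,16
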