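series,rp_t,rp_m,rp_a
DYS19,0.52,0.527473,0.530303
DYS385a,0.698006,0.703297,0.692308
DYS385b,0.777778,0.802198,0.75641
DYS389I,0.54416,0.604396,0.512821
DYS389b,0.64,0.648352,0.581818
DYS390,0.717949,0.692308,0.730769
DYS391,0.5671,0.604396,0.464286
DYS392,0.453333,0.527473,0.327273
DYS393,0.581197,0.582418,0.5
DYS437,0.655271,0.648352,0.705128
DYS438,0.643875,0.659341,0.653846
DYS439,0.612536,0.615385,0.5
DYS448,0.5,0.494506,0.545455
DYS456,0.632479,0.648352,0.653846
DYS458,0.735043,0.736264,0.74359
DYS635,0.772308,0.835165,0.712121
YGATAH4,0.492308,0.527473,0.484849
DYS460,0.501425,0.538462,0.461539
DYS533,0.571429,0.615385,0.476191
DYS481,0.737892,0.769231,0.730769
DYS576,0.735043,0.692308,0.730769
DYF387S1a,0.621083,0.604396,0.653846
DYF387S1b,0.723647,0.747253,0.717949
DYS449,0.757835,0.747253,0.794872
DYS518,0.76,0.758242,0.818182
DYS570,0.700855,0.78022,0.653846
DYS627,0.621083,0.659341,0.602564
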