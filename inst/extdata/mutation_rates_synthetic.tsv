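series	rate
DYS19	0.002
DYS385a	0.002
DYS385b	0.002
DYS389I	0.002
DYS389b	0.002
DYS390	0.002
DYS391	0.002
DYS392	0.002
DYS393	0.002
DYS437	0.002
DYS438	0.002
DYS439	0.002
DYS448	0.002
DYS456	0.002
DYS458	0.002
DYS635	0.002
YGATAH4	0.002
DYS460	0.004
DYS481	0.004
DYS533	0.004
DYF387S1a	0.012
DYF387S1b	0.012
DYS449	0.012
DYS518	0.012
DYS570	0.012
DYS576	0.012
DYS627	0.012
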