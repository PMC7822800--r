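name,density
air,0.0012047
water,1
soft_tissue,1.06
adipose,0.95
bone,1.55
brain,1.04
lung,0.26
aluminum,2.699
copper,8.96
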