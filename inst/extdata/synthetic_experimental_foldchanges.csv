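node,group,fold_change
uprmt_hsp60,mid,0.95
uprer_bip,mid,1.05
uprer_pperk,mid,1.10
skn1,mid,1.30
daf16,mid,1.25
sod2,mid,1.20
bec1,mid,1.05
mtor,mid,0.90
pink1,mid,1.10
uprmt_hsp60,late,0.80
uprer_bip,late,0.95
uprer_pperk,late,1.15
skn1,late,1.60
daf16,late,1.55
sod2,late,1.35
bec1,late,0.95
mtor,late,0.75
pink1,late,1.20
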