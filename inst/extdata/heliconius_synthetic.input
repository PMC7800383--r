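tree ((((inv1:0.5,inv2:0.5):0.1,(anc1:0.55,anc2:0.55):0.05):0.8,(inv3:0.6,inv4:0.6):0.8):1.75,out:3.15);
introgression inv3 inv2 0.15 0.091
introgression inv1 inv3 0.3 0.11
derived inv1 inv2 inv3 inv4
outgroup out
rate 0.005
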