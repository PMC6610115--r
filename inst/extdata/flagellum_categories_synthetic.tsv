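category	focal_nonmotile	relative_nonmotile
tubulin	2	2
radial_spoke	2	1
central_pair	6	4
outer_dynein_arm	6	4
inner_dynein_arm	4	2
IFT_A_complex	2	0
IFT_B_complex	7	4
BBSome	0	0
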