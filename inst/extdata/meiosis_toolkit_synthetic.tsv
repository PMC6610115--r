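seq_id	gene	category	is_decoy
Spo11-2_ref	Spo11-2	meiosis	FALSE
Mer3_ref	Mer3	meiosis	FALSE
Hop1_ref	Hop1	meiosis	FALSE
Dmc1_ref	Dmc1	meiosis	FALSE
Hop2_ref	Hop2	meiosis	FALSE
Mnd1_ref	Mnd1	meiosis	FALSE
Msh4_ref	Msh4	meiosis	FALSE
Msh5_ref	Msh5	meiosis	FALSE
Rec8_ref	Rec8	meiosis	FALSE
Rec8_decoy	Rec8	meiosis	TRUE
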