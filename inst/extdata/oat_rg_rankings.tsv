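sample_set	method	gene	rank
all_samples	delta_ct	18S	1
all_samples	delta_ct	EIF4A	2
all_samples	delta_ct	TBC	3
all_samples	delta_ct	UBQ10	4
all_samples	delta_ct	UBC21	5
all_samples	delta_ct	HNR	6
all_samples	delta_ct	EF1A	7
all_samples	delta_ct	EP	8
all_samples	delta_ct	PP2A	9
all_samples	delta_ct	GAPDH1	10
all_samples	genorm	HNR	1
all_samples	genorm	EIF4A	2
all_samples	genorm	EF1A	3
all_samples	genorm	PP2A	4
all_samples	genorm	UBC21	5
all_samples	genorm	TBC	6
all_samples	genorm	EP	7
all_samples	genorm	GAPDH1	8
all_samples	genorm	UBQ10	9
all_samples	genorm	18S	10
all_samples	normfinder	EIF4A	1
all_samples	normfinder	HNR	2
all_samples	normfinder	EF1A	3
all_samples	normfinder	UBC21	4
all_samples	normfinder	PP2A	5
all_samples	normfinder	TBC	6
all_samples	normfinder	GAPDH1	7
all_samples	normfinder	EP	8
all_samples	normfinder	UBQ10	9
all_samples	normfinder	18S	10
all_samples	bestkeeper	18S	1
all_samples	bestkeeper	EIF4A	2
all_samples	bestkeeper	UBQ10	3
all_samples	bestkeeper	TBC	4
all_samples	bestkeeper	HNR	5
all_samples	bestkeeper	GAPDH1	6
all_samples	bestkeeper	UBC21	7
all_samples	bestkeeper	EF1A	8
all_samples	bestkeeper	EP	9
all_samples	bestkeeper	PP2A	10
seedlings	delta_ct	UBC21	1
seedlings	delta_ct	GAPDH1	2
seedlings	delta_ct	EP	3
seedlings	delta_ct	HNR	4
seedlings	delta_ct	EF1A	5
seedlings	delta_ct	UBQ10	6
seedlings	delta_ct	EIF4A	7
seedlings	delta_ct	PP2A	8
seedlings	delta_ct	18S	9
seedlings	delta_ct	TBC	10
seedlings	genorm	EIF4A	1
seedlings	genorm	HNR	2
seedlings	genorm	EP	3
seedlings	genorm	UBQ10	4
seedlings	genorm	PP2A	5
seedlings	genorm	EF1A	6
seedlings	genorm	UBC21	7
seedlings	genorm	TBC	8
seedlings	genorm	18S	9
seedlings	genorm	GAPDH1	10
seedlings	normfinder	HNR	1
seedlings	normfinder	PP2A	2
seedlings	normfinder	UBC21	3
seedlings	normfinder	EIF4A	4
seedlings	normfinder	EP	5
seedlings	normfinder	UBQ10	6
seedlings	normfinder	EF1A	7
seedlings	normfinder	TBC	8
seedlings	normfinder	GAPDH1	9
seedlings	normfinder	18S	10
seedlings	bestkeeper	UBC21	1
seedlings	bestkeeper	EP	2
seedlings	bestkeeper	GAPDH1	3
seedlings	bestkeeper	EF1A	4
seedlings	bestkeeper	HNR	5
seedlings	bestkeeper	EIF4A	6
seedlings	bestkeeper	UBQ10	7
seedlings	bestkeeper	PP2A	8
seedlings	bestkeeper	18S	9
seedlings	bestkeeper	TBC	10
seeds	delta_ct	18S	1
seeds	delta_ct	TBC	2
seeds	delta_ct	EIF4A	3
seeds	delta_ct	EP	4
seeds	delta_ct	HNR	5
seeds	delta_ct	UBC21	6
seeds	delta_ct	PP2A	7
seeds	delta_ct	EF1A	8
seeds	delta_ct	UBQ10	9
seeds	delta_ct	GAPDH1	10
seeds	genorm	EF1A	1
seeds	genorm	EP	2
seeds	genorm	HNR	3
seeds	genorm	PP2A	4
seeds	genorm	EIF4A	5
seeds	genorm	UBC21	6
seeds	genorm	TBC	7
seeds	genorm	UBQ10	8
seeds	genorm	GAPDH1	9
seeds	genorm	18S	10
seeds	normfinder	EF1A	1
seeds	normfinder	EP	2
seeds	normfinder	HNR	3
seeds	normfinder	PP2A	4
seeds	normfinder	EIF4A	5
seeds	normfinder	UBC21	6
seeds	normfinder	TBC	7
seeds	normfinder	UBQ10	8
seeds	normfinder	GAPDH1	9
seeds	normfinder	18S	10
seeds	bestkeeper	18S	1
seeds	bestkeeper	EIF4A	2
seeds	bestkeeper	TBC	3
seeds	bestkeeper	EP	4
seeds	bestkeeper	HNR	5
seeds	bestkeeper	UBQ10	6
seeds	bestkeeper	PP2A	7
seeds	bestkeeper	UBC21	8
seeds	bestkeeper	EF1A	9
seeds	bestkeeper	GAPDH1	10
endosperms	delta_ct	18S	1
endosperms	delta_ct	EIF4A	2
endosperms	delta_ct	TBC	3
endosperms	delta_ct	UBC21	4
endosperms	delta_ct	EP	5
endosperms	delta_ct	HNR	6
endosperms	delta_ct	UBQ10	7
endosperms	delta_ct	PP2A	8
endosperms	delta_ct	EF1A	9
endosperms	delta_ct	GAPDH1	10
endosperms	genorm	HNR	1
endosperms	genorm	PP2A	2
endosperms	genorm	UBC21	3
endosperms	genorm	EIF4A	4
endosperms	genorm	EP	5
endosperms	genorm	EF1A	6
endosperms	genorm	UBQ10	7
endosperms	genorm	GAPDH1	8
endosperms	genorm	TBC	9
endosperms	genorm	18S	10
endosperms	normfinder	EIF4A	1
endosperms	normfinder	HNR	2
endosperms	normfinder	UBQ10	3
endosperms	normfinder	EP	4
endosperms	normfinder	PP2A	5
endosperms	normfinder	EF1A	6
endosperms	normfinder	UBC21	7
endosperms	normfinder	TBC	8
endosperms	normfinder	18S	9
endosperms	normfinder	GAPDH1	10
endosperms	bestkeeper	18S	1
endosperms	bestkeeper	EIF4A	2
endosperms	bestkeeper	TBC	3
endosperms	bestkeeper	UBC21	4
endosperms	bestkeeper	HNR	5
endosperms	bestkeeper	EP	6
endosperms	bestkeeper	PP2A	7
endosperms	bestkeeper	EF1A	8
endosperms	bestkeeper	UBQ10	9
endosperms	bestkeeper	GAPDH1	10
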