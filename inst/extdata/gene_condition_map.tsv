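# Gene -> condition map used by cohort summarization. Editable.
gene	condition
TYR	OCA
OCA2	OCA
TYRP1	OCA
SLC45A2	OCA
SLC24A5	OCA
LRMDA	OCA
DCT	OCA
HPS1	HPS
HPS3	HPS
HPS4	HPS
HPS5	HPS
HPS6	HPS
AP3B1	HPS
AP3D1	HPS
BLOC1S3	HPS
BLOC1S5	HPS
BLOC1S6	HPS
DTNBP1	HPS
LYST	CHS
GPR143	OA
MLPH	GS
MYO5A	GS
RAB27A	GS
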