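# path: LECA > Opisthokonta > Fungi_basal > Dikarya > Saccharomycotina > post_Yarrowia > Saccharomyces_cerevisiae
node	kind	family	uncertain
Fungi_basal	loss	Rab14	FALSE
Fungi_basal	loss	Rab21	FALSE
Fungi_basal	loss	Rab22	FALSE
Fungi_basal	loss	Rab24	FALSE
Fungi_basal	loss	Rab28	FALSE
Fungi_basal	loss	Rab29	FALSE
Fungi_basal	loss	Rab7L1	FALSE
Dikarya	loss	Rab23	FALSE
Dikarya	loss	Rab32	FALSE
Dikarya	loss	RabL4	FALSE
Saccharomycotina	loss	Rab18	FALSE
post_Yarrowia	loss	Rab2	FALSE
post_Yarrowia	loss	Rab4	FALSE
post_Yarrowia	loss	RabX1	FALSE
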