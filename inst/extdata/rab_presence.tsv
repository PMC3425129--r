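family	Metazoa	Choanoflagellata	Fungi	Amoebozoa	Heterolobosea	Kinetoplastida	Chlorophyta	Streptophyta	Heterokonta	Apicomplexa
Rab1	1	1	1	1	1	1	1	1	1	1
Rab2	1	1	1	1	1	1	1	1	1	1
Rab4	1	1	1	1	1	1	1	1	1	1
Rab5	1	1	1	1	1	1	1	1	1	1
Rab6	1	1	1	1	1	1	1	1	1	1
Rab7	1	1	1	1	1	1	1	1	1	1
Rab8	1	1	1	1	1	0	1	1	1	1
Rab11	1	1	1	1	1	1	1	1	1	1
Rab14	1	1	0	1	1	1	0	0	1	1
Rab18	1	1	1	1	1	1	1	1	1	1
Rab21	1	1	0	1	1	1	1	1	1	1
Rab22	1	1	0	1	1	0	0	0	1	0
Rab23	1	1	1	1	1	1	1	1	1	0
Rab24	1	0	0	0	1	0	1	0	0	0
Rab28	1	1	0	1	1	1	1	0	1	0
Rab29	1	1	0	0	1	0	0	0	0	0
Rab32	1	1	1	1	1	1	0	0	1	0
RabL4	1	1	1	0	1	0	1	0	1	0
RabX1	1	0	1	0	1	0	0	0	1	0
Rab7L1	1	1	0	1	1	0	0	0	1	0
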