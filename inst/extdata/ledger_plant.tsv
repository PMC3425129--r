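# path: LECA > Archaeplastida > Chlorophyta > Streptophyta > Angiospermae
node	kind	family	uncertain
Archaeplastida	loss	Rab14	FALSE
Archaeplastida	loss	Rab22	FALSE
Archaeplastida	loss	Rab29	FALSE
Archaeplastida	loss	Rab32	FALSE
Archaeplastida	loss	Rab7L1	FALSE
Archaeplastida	loss	RabX1	FALSE
Streptophyta	loss	Rab24	FALSE
Streptophyta	loss	Rab28	FALSE
Streptophyta	loss	RabL4	FALSE
Angiospermae	loss	Rab23	FALSE
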