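taxon	supergroup
Metazoa	Unikonta
Choanoflagellata	Unikonta
Fungi	Unikonta
Amoebozoa	Unikonta
Heterolobosea	Excavata
Kinetoplastida	Excavata
Chlorophyta	Archaeplastida
Streptophyta	Archaeplastida
Heterokonta	SAR+CCTH
Apicomplexa	SAR+CCTH
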