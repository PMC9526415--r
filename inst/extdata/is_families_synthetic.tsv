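family	tir_min	tir_max	element_min	element_max
IS3	15	45	700	3500
IS5	15	45	700	3500
IS6	15	45	700	3500
IS21	15	45	700	3500
IS30	15	45	700	3500
IS66	15	45	700	3500
IS110	15	45	700	3500
IS256	15	45	700	3500
IS481	15	45	700	3500
IS630	15	45	700	3500
ISL3	15	45	700	3500
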