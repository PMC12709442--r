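dinucleotide	score
AA	4.5
AT	1.0
AC	4.0
AG	6.5
CA	14.0
CC	5.5
CG	24.0
GA	9.5
GC	11.5
TA	10.0
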