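# Donor (5'ss) position weight matrix: 9-mer, positions -3..-1 exonic,
# +1..+6 intronic. Probabilities per position sum to 1. Built from canonical
# human donor-site base frequencies (consensus [CA]AG|GTAAGT), floored away
# from zero so every window has a finite log-odds score.
pos	A	C	G	T
-3	0.35	0.36	0.18	0.11
-2	0.60	0.13	0.13	0.14
-1	0.09	0.03	0.80	0.08
+1	0.001	0.001	0.997	0.001
+2	0.001	0.001	0.001	0.997
+3	0.59	0.03	0.35	0.03
+4	0.71	0.08	0.12	0.09
+5	0.06	0.05	0.84	0.05
+6	0.15	0.16	0.21	0.48
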