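# Acceptor (3'ss) position weight matrix: 23-mer, positions -20..-1 intronic
# (polypyrimidine tract ending in the invariant AG) and +1..+3 exonic.
# Probabilities per position sum to 1; canonical human acceptor-site base
# frequencies, floored away from zero.
pos	A	C	G	T
-20	0.10	0.31	0.13	0.46
-19	0.10	0.31	0.13	0.46
-18	0.10	0.31	0.13	0.46
-17	0.10	0.31	0.13	0.46
-16	0.10	0.31	0.13	0.46
-15	0.10	0.31	0.13	0.46
-14	0.10	0.31	0.13	0.46
-13	0.10	0.31	0.13	0.46
-12	0.10	0.31	0.13	0.46
-11	0.10	0.31	0.13	0.46
-10	0.10	0.31	0.13	0.46
-9	0.10	0.31	0.13	0.46
-8	0.10	0.31	0.13	0.46
-7	0.10	0.31	0.13	0.46
-6	0.08	0.36	0.08	0.48
-5	0.07	0.36	0.06	0.51
-4	0.24	0.28	0.25	0.23
-3	0.05	0.64	0.01	0.30
-2	0.997	0.001	0.001	0.001
-1	0.001	0.001	0.997	0.001
+1	0.25	0.14	0.50	0.11
+2	0.26	0.26	0.24	0.24
+3	0.25	0.25	0.25	0.25
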