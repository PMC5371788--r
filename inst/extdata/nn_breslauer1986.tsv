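# Nearest-neighbor parameters (Breslauer 1986).
# dH in kcal/mol, dS in cal/(mol*K). Initiation is a single duplex term of
# dS -10.8, split evenly over the two termini so the per-terminal scheme of
# the unified set applies to both tables.
term	dH	dS
AA	-9.1	-24.0
AT	-8.6	-23.9
TA	-6.0	-16.9
CA	-5.8	-12.9
GT	-6.5	-17.3
CT	-7.8	-20.8
GA	-5.6	-13.5
CG	-11.9	-27.8
GC	-11.1	-26.7
GG	-11.0	-26.6
TT	-9.1	-24.0
TG	-5.8	-12.9
AC	-6.5	-17.3
AG	-7.8	-20.8
TC	-5.6	-13.5
CC	-11.0	-26.6
init_AT	0	-5.4
init_GC	0	-5.4
sym	0	-1.4
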