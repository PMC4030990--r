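# Published reference energies for the packaged benchmark sequences.
# label: E_bench = benchmark minimum (3D cubic), E_nat = native/optimal
# value for the stated lattice-model pair, E_pub = best published value.
id	lattice	model	label	energy
HP1	cubic	hp	E_bench	-32
HP1	fcc	hp	E_nat	-69
HP2	cubic	hp	E_bench	-34
HP2	fcc	hp	E_nat	-69
HP3	cubic	hp	E_bench	-34
HP3	fcc	hp	E_nat	-72
HP4	cubic	hp	E_bench	-33
HP4	fcc	hp	E_nat	-71
HP5	cubic	hp	E_bench	-32
HP5	fcc	hp	E_nat	-70
HP6	cubic	hp	E_bench	-32
HP6	fcc	hp	E_nat	-70
HP7	cubic	hp	E_bench	-32
HP7	fcc	hp	E_nat	-70
HP8	cubic	hp	E_bench	-31
HP8	fcc	hp	E_nat	-69
HP9	cubic	hp	E_bench	-34
HP9	fcc	hp	E_nat	-71
HP10	cubic	hp	E_bench	-33
HP10	fcc	hp	E_nat	-68
MJ1	cubic	contact	E_nat	-25.85
MJ2	cubic	contact	E_nat	-25.92
MJ3	cubic	contact	E_nat	-26.09
MJ4	cubic	contact	E_nat	-25.87
MJ5	cubic	contact	E_nat	-26.15
MJ6	cubic	contact	E_nat	-26.24
4RXN	fcc	contact	E_pub	-166.88
1ENH	fcc	contact	E_pub	-153.79
4PTI	fcc	contact	E_pub	-210.29
2IGD	fcc	contact	E_pub	-183.18
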