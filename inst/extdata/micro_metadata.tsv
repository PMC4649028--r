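sample_id	depth	compartment	replicate
topsoil.bulk.1	topsoil	bulk	1
topsoil.bulk.2	topsoil	bulk	2
topsoil.bulk.3	topsoil	bulk	3
topsoil.drilosphere.1	topsoil	drilosphere	1
topsoil.drilosphere.2	topsoil	drilosphere	2
topsoil.drilosphere.3	topsoil	drilosphere	3
topsoil.rhizosphere.1	topsoil	rhizosphere	1
topsoil.rhizosphere.2	topsoil	rhizosphere	2
topsoil.rhizosphere.3	topsoil	rhizosphere	3
subsoil.bulk.1	subsoil	bulk	1
subsoil.bulk.2	subsoil	bulk	2
subsoil.bulk.3	subsoil	bulk	3
subsoil.drilosphere.1	subsoil	drilosphere	1
subsoil.drilosphere.2	subsoil	drilosphere	2
subsoil.drilosphere.3	subsoil	drilosphere	3
subsoil.rhizosphere.1	subsoil	rhizosphere	1
subsoil.rhizosphere.2	subsoil	rhizosphere	2
subsoil.rhizosphere.3	subsoil	rhizosphere	3
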