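label	Group	numOtus	Otu01	Otu02	Otu03	Otu04	Otu05	Otu06	Otu07	Otu08	Otu09	Otu10	Otu11	Otu12
0.05	topsoil.bulk.1	12	60	12	0	1	20	20	7	0	5	0	0	0
0.05	topsoil.bulk.2	12	60	12	0	1	20	20	7	0	5	0	0	0
0.05	topsoil.bulk.3	12	60	12	0	1	20	20	0	0	5	0	0	0
0.05	topsoil.drilosphere.1	12	60	12	0	25	20	0	7	0	5	0	0	0
0.05	topsoil.drilosphere.2	12	60	12	0	25	20	0	7	0	5	0	0	0
0.05	topsoil.drilosphere.3	12	60	12	0	25	20	0	0	0	5	0	0	0
0.05	topsoil.rhizosphere.1	12	60	12	40	1	20	0	7	0	0	0	0	0
0.05	topsoil.rhizosphere.2	12	60	12	40	1	20	0	0	0	0	0	0	0
0.05	topsoil.rhizosphere.3	12	60	12	40	1	20	0	0	0	0	0	0	0
0.05	subsoil.bulk.1	12	60	12	0	1	0	20	0	6	0	0	0	3
0.05	subsoil.bulk.2	12	60	12	0	1	0	20	0	6	0	0	0	3
0.05	subsoil.bulk.3	12	60	12	0	1	0	20	0	5	0	0	0	3
0.05	subsoil.drilosphere.1	12	60	12	0	25	0	0	0	0	0	0	4	3
0.05	subsoil.drilosphere.2	12	60	12	0	25	0	0	0	0	0	0	4	3
0.05	subsoil.drilosphere.3	12	60	12	0	25	0	0	0	0	0	0	0	3
0.05	subsoil.rhizosphere.1	12	60	12	40	1	0	0	0	0	0	1	0	3
0.05	subsoil.rhizosphere.2	12	60	12	40	1	0	0	0	0	0	0	0	3
0.05	subsoil.rhizosphere.3	12	60	12	40	1	0	0	0	0	0	0	0	3
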