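otu_id	topsoil.bulk.1	topsoil.bulk.2	topsoil.bulk.3	topsoil.drilosphere.1	topsoil.drilosphere.2	topsoil.drilosphere.3	topsoil.rhizosphere.1	topsoil.rhizosphere.2	topsoil.rhizosphere.3	subsoil.bulk.1	subsoil.bulk.2	subsoil.bulk.3	subsoil.drilosphere.1	subsoil.drilosphere.2	subsoil.drilosphere.3	subsoil.rhizosphere.1	subsoil.rhizosphere.2	subsoil.rhizosphere.3
Otu01	60	60	60	60	60	60	60	60	60	60	60	60	60	60	60	60	60	60
Otu02	12	12	12	12	12	12	12	12	12	12	12	12	12	12	12	12	12	12
Otu03	0	0	0	0	0	0	40	40	40	0	0	0	0	0	0	40	40	40
Otu04	1	1	1	25	25	25	1	1	1	1	1	1	25	25	25	1	1	1
Otu05	20	20	20	20	20	20	20	20	20	0	0	0	0	0	0	0	0	0
Otu06	20	20	20	0	0	0	0	0	0	20	20	20	0	0	0	0	0	0
Otu07	7	7	0	7	7	0	7	0	0	0	0	0	0	0	0	0	0	0
Otu08	0	0	0	0	0	0	0	0	0	6	6	5	0	0	0	0	0	0
Otu09	5	5	5	5	5	5	0	0	0	0	0	0	0	0	0	0	0	0
Otu10	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0
Otu11	0	0	0	0	0	0	0	0	0	0	0	0	4	4	0	0	0	0
Otu12	0	0	0	0	0	0	0	0	0	3	3	3	3	3	3	3	3	3
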