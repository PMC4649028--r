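OTU	Size	Taxonomy
Otu01	1080	Bacteria(100);Actinobacteria(100);ClassA(100);OrderA(100);FamilyA(100);GenusA(100);
Otu02	216	Bacteria(100);Proteobacteria(100);ClassB(100);OrderB(100);FamilyB(100);GenusB(100);
Otu03	240	Bacteria(100);Proteobacteria(100);ClassB(100);OrderB(100);FamilyB(100);GenusC(100);
Otu04	162	Bacteria(100);Bacteroidetes(100);ClassC(100);OrderC(100);FamilyC(100);GenusD(100);
Otu05	180	Bacteria(100);Actinobacteria(100);ClassA(100);OrderA(100);FamilyA(100);unclassified(100);
Otu06	120	Bacteria(100);Acidobacteria(100);ClassD(100);OrderD(100);unclassified(100);unclassified(100);
Otu07	35	Bacteria(100);Verrucomicrobia(100);ClassE(100);OrderE(100);FamilyE(100);GenusE(100);
Otu08	17	Bacteria(100);Planctomycetes(100);ClassF(100);OrderF(100);FamilyF(100);GenusF(100);
Otu09	30	Bacteria(100);unclassified(100);unclassified(100);unclassified(100);unclassified(100);unclassified(100);
Otu10	1	Bacteria(100);Firmicutes(100);ClassG(100);OrderG(100);FamilyG(100);GenusG(100);
Otu11	8	Bacteria(100);Chloroflexi(100);ClassH(100);OrderH(100);FamilyH(100);GenusH(100);
Otu12	27	Bacteria(100);Gemmatimonadetes(100);ClassI(100);OrderI(100);FamilyI(100);GenusI(100);
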