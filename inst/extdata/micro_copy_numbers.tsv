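rank	name	mean_copies
genus	GenusA	2
genus	GenusB	4
genus	GenusC	4
genus	GenusD	6
family	FamilyA	3
order	OrderD	1.5
domain	Bacteria	4.2
root	root	4.2
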