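code	display	parents
B01A	Antithrombotic agents
B01AA	Vitamin K antagonists	B01A
B01AA03	Warfarin	B01AA
B01AB	Heparin group	B01A
B01AB01	Heparin	B01AB
B01AF	Direct factor Xa inhibitors	B01A
B01AF01	Rivaroxaban	B01AF
B01AD	Enzymes (fibrinolytics)	B01A
B01AD02	Alteplase	B01AD
N02BE01	Paracetamol
B05BB01	Electrolyte solution
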