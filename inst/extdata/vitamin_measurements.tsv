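vitamin	organism	value	unit
biotin	Escherichia coli	4.0e-5	molar
cobalamin	Lactobacillus reuteri CE	5.0e-5	mass_per_volume
folate	Lactobacillus casei	2.2e-5	molar
niacin	Escherichia coli	1.12e6	molecules_per_cell
pantothenate	Escherichia coli	1.0e-6	molar
pyridoxine	Escherichia coli	1.5e-10	production_rate_per_mgdw
riboflavin	Escherichia coli	4.0e-6	molar
thiamin	Lactobacillus fermenti	3.0e-6	mass_per_gdw
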