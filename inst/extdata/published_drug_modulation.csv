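drug,gene_symbol,modulation
Carbamazepine,GAD1,decreases
Lithium,GAD1,decreases
Omega-3 fatty acids,GAD1,decreases
Valproate,GAD1,decreases
Clozapine,NTRK3,decreases
Carbamazepine,ADRA2A,decreases
Clozapine,ADRA2A,decreases
Norfluoxetine,ADRA2A,decreases
Valproate,ADRA2A,decreases
Aripiprazole,FZD10,decreases
Fluoxetine,FZD10,decreases
Gamma Frequency,FZD10,decreases
Clozapine,GRK4,decreases
Gamma Frequency,GRK4,decreases
Acetyldigitoxin,ATP1B2,decreases
Clozapine,ATP1B2,decreases
Deslanoside,ATP1B2,decreases
Digitoxin,ATP1B2,decreases
Digoxin,ATP1B2,decreases
Haloperidol,ATP1B2,decreases
Lithium,ATP1B2,decreases
Valproate,ATP1B2,decreases
Clozapine,CLIC6,decreases
Omega-3 fatty acids,CLIC6,decreases
Gamma Frequency,CLIC6,decreases
Omega-3 fatty acids,EFNA5,decreases
Gamma Frequency,EFNA5,decreases
Mianserin,GPX7,increases
S-adenosyl methionine (SAM),GPX7,increases
Fluoxetine,SLC6A2,decreases
Norfluoxetine,SLC6A2,decreases
Agomelatine,SLC6A4,decreases
Benzodiazepines,SLC6A4,decreases
Citalopram,SLC6A4,decreases
Clozapine,SLC6A4,decreases
Omega-3 fatty acids,SLC6A4,decreases
Oxycodone,SLC6A4,decreases
Sertraline,SLC6A4,decreases
Vortioxetine,SLC6A4,decreases
Antidepressants,TMEM138,increases
Clozapine,CCKBR,decreases
Benzodiazepines,DYNLL2,increases
Valproate,DYNLL2,increases
Ketamine,NRG1,decreases
Antipsychotics,NRG1,decreases
Valproate,NRG1,decreases
Lithium,NRG1,decreases
Valproate,TFRC,increases
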