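class,source
"ACE inhibitors, plain",ATC
Adrenergic Uptake Inhibitors,MESH
Adrenergic and dopaminergic agents,ATC
Aldosterone antagonists,ATC
Alpha and beta blocking agents,ATC
Alpha glucosidase inhibitors,ATC
Alpha-adrenoreceptor antagonists,ATC
Aminoketone,"DAILYMED,FDASPL"
"Angiotensin II antagonists, plain",ATC
Anti-Anxiety Agents,MESH
Anti-epileptic Agent,"DAILYMED,FDASPL"
"Antiarrhythmics, class III",ATC
"Antiarrhythmics, class Ib",ATC
"Antiarrhythmics, class Ic",ATC
Anticholinesterases,ATC
Antidepressive Agents,MESH
"Antidepressive Agents, Second-Generation",MESH
"Antidepressive Agents, Tricyclic",MESH
Antihistamine,"DAILYMED,FDASPL"
Antipsychotic Agents,MESH
Atypical Antipsychotic,"DAILYMED,FDASPL"
Azaspirodecanedione derivatives,ATC
Barbiturates and derivatives,ATC
Benzodiazepine,"DAILYMED,FDASPL"
Benzodiazepine related drugs,ATC
Benzothiazepine derivatives,ATC
"Beta blocking agents, non-selective",ATC
"Beta blocking agents, selective",ATC
Biguanides,"ATC,DAILYMED,FDASPL"
Bile acid sequestrants,ATC
Butyrophenone derivatives,ATC
Carboxamide derivatives,ATC
Central Nervous System Depressants,MESH
Central Nervous System Stimulant,"DAILYMED,FDASPL"
Centrally acting sympathomimetics,ATC
Corticosteroids,ATC
"Diazepines, oxazepines, thiazepines and oxepines",ATC
Digitalis glycosides,ATC
Dihydropyridine derivatives,ATC
Dipeptidyl peptidase 4 (DPP-4) inhibitors,ATC
Diphenylmethane derivatives,ATC
Ergot alkaloids,ATC
Fibrates,ATC
Fish Oils,NDFRT
HMG CoA reductase inhibitors,ATC
Heparins or heparinoids for topical use,ATC
Hydantoin derivatives,ATC
Imidazoline receptor agonists,ATC
Insulin,"DAILYMED,FDASPL,NDFRT"
Lithium,"ATC,NDFRT"
Local anesthetics,ATC
Melatonin receptor agonists,ATC
Mood Stabilizer,"DAILYMED,FDASPL"
Muscle relaxants,ATC
Nicotinic acid and derivatives,ATC
Nonsteroidal Anti-inflammatory Drug,"DAILYMED,FDASPL"
Norepinephrine Reuptake Inhibitor,"DAILYMED,FDASPL"
Organic nitrates,ATC
Other anti-dementia drugs,ATC
Other antidepressants,ATC
Other antipsychotics,ATC
"Other blood glucose lowering drugs, excl. insulins",ATC
Other cardiac preparations,ATC
Other lipid modifying agents,ATC
Other potassium-sparing agents,ATC
Other psychostimulants and nootropics,ATC
Phenothiazines with piperazine structure,ATC
Phenylalkylamine derivatives,ATC
Purine derivatives,ATC
Pyrimidine derivatives,ATC
Renin-inhibitors,ATC
Serotonin Reuptake Inhibitor,"DAILYMED,FDASPL"
Serotonin and Norepinephrine Reuptake Inhibitor,"DAILYMED,FDASPL"
"Sulfonamides, plain",ATC
Sulfonylureas,ATC
Sympathomimetic-like Agent,"DAILYMED,FDASPL"
"Thiazides, plain",ATC
Thiazolidinediones,"ATC,DAILYMED,FDASPL"
Thyroid Hormone Receptor Agonists,NDFRT
Thyroid Hormone Synthesis Inhibitor,"DAILYMED,FDASPL"
Typical Antipsychotic,"DAILYMED,FDASPL"
Tyrosine,NDFRT
Vasodilator Agents,MESH
l-Thyroxine,"DAILYMED,FDASPL"
l-Triiodothyronine,"DAILYMED,FDASPL"
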