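# Code sets referenced by the shipped rule library and the data-quality
# probe suite.  Drug classes are ATC prefixes; diagnosis groups are
# ICD-9 prefixes matched against the literal stored code string (dotted
# where the stored codes are dotted).  These are conventional mappings:
# published prescribing criteria are not defined in terms of reference
# terminologies, so any deployment must supply its own reviewed sets.

# --- drug classes (rule anchors and drug-drug extras) ---
benzodiazepines:          {system: ATC, prefixes: [N05BA, N05CD]}
tricyclic_antidepressants: {system: ATC, prefixes: [N06AA]}
first_gen_antihistamines: {system: ATC, prefixes: [R06AB, R06AD]}
opioids:                  {system: ATC, prefixes: [N02A]}
nsaids:                   {system: ATC, prefixes: [M01A]}
aspirin:                  {system: ATC, prefixes: [B01AC06, N02BA01]}
warfarin:                 {system: ATC, prefixes: [B01AA03]}
loop_diuretics:           {system: ATC, prefixes: [C03C]}
thiazide_diuretics:       {system: ATC, prefixes: [C03A]}
beta_blockers:            {system: ATC, prefixes: [C07A]}
verapamil:                {system: ATC, prefixes: [C08DA01]}
diltiazem:                {system: ATC, prefixes: [C08DB01]}
digoxin:                  {system: ATC, prefixes: [C01AA05]}
antipsychotics:           {system: ATC, prefixes: [N05A]}
ssri:                     {system: ATC, prefixes: [N06AB]}
metoclopramide:           {system: ATC, prefixes: [A03FA01]}
bladder_antimuscarinics:  {system: ATC, prefixes: [G04BD]}
estrogens:                {system: ATC, prefixes: [G03C]}
systemic_corticosteroids: {system: ATC, prefixes: [H02AB]}

# --- drugs named by the concordance probes ---
tiotropium:               {system: ATC, prefixes: [R03BB04]}
levothyroxine:            {system: ATC, prefixes: [H03AA01]}
anti_gout:                {system: ATC, prefixes: [M04A]}

# --- diagnosis groups (rule extras) ---
falls_history:            {system: ICD9, prefixes: [E885, E886, E888, V15.88]}
dementia:                 {system: ICD9, prefixes: ['290', '294.1', '331.0']}
glaucoma:                 {system: ICD9, prefixes: ['365']}
chronic_constipation:     {system: ICD9, prefixes: ['564.0']}
parkinsonism:             {system: ICD9, prefixes: ['332']}
peptic_ulcer:             {system: ICD9, prefixes: ['531', '532', '533', '534']}
heart_failure:            {system: ICD9, prefixes: ['428']}
chronic_kidney_disease:   {system: ICD9, prefixes: ['585']}
hypertension:             {system: ICD9, prefixes: ['401']}
urinary_incontinence:     {system: ICD9, prefixes: ['788.3']}
hyponatremia:             {system: ICD9, prefixes: ['276.1']}
cardiac_conduction_disease: {system: ICD9, prefixes: ['426']}
gi_bleeding_history:      {system: ICD9, prefixes: ['578']}
venous_thromboembolism:   {system: ICD9, prefixes: ['451', '453', '415.1']}
benign_prostatic_hyperplasia: {system: ICD9, prefixes: ['600']}
coronary_artery_disease:  {system: ICD9, prefixes: ['410', '411', '412', '413', '414']}

# --- diagnosis groups named by the probes ---
diabetes:                 {system: ICD9, prefixes: ['250']}
copd:                     {system: ICD9, prefixes: ['491', '492', '496']}
hypothyroidism:           {system: ICD9, prefixes: ['244']}
gout:                     {system: ICD9, prefixes: ['274']}
epilepsy:                 {system: ICD9, prefixes: ['345']}
breast_cancer:            {system: ICD9, prefixes: ['174']}
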