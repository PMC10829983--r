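Source,Edge,Target
ICS,included,SABA corticosteroid
Increase frequency,add,SABA spacer
acute care Patients,monitored,little SABA treatment
severe asthma,improve,SABA alone
ideally SABA reliever,Reducing,important asthma treatment
current GINA,recommends,serious dose ICS exacerbations
SABA,include,separate inhalers
Older inhaler patients,may,multiple inhaler devices
poor inhaler diagnosis,appear,incorrect inhaler technique
symptoms,relieved,inhaled bronchodilator
Oral bronchodilator therapy,recommended,inhaled SABA
Reslizumab benralizumab,binds to,cell eosinophils
Mechanism,signaling,interleukin-4 receptor IL-4
Clinician receptor judgment,used,worsening receptor asthma
eosinophilic airway patients,respond,corticosteroid asthma treatment
needed ICS formoterol,delivered,symptom relief
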