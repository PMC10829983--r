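{
  "verbs": ["binds", "include", "included", "includes", "recommends",
            "recommended", "improve", "improves", "reduces", "Reducing",
            "relieved", "relieves", "treats", "causes", "triggers",
            "monitored", "delivered", "respond", "appear", "add", "used",
            "signaling", "may", "is", "are", "Am", "suggests", "worsens",
            "induces", "inhibits", "blocks", "targets", "controls",
            "prevents", "increases", "decreases", "characterizes",
            "accompanies", "precedes", "follows", "exacerbates",
            "associated", "involves"],
  "adpositions": ["to", "with", "in", "by", "for", "of", "from", "on"],
  "drugs": ["budesonide", "formoterol", "salbutamol", "tiotropium",
            "dupilumab", "reslizumab", "mepolizumab", "benralizumab",
            "omalizumab", "beclomethasone", "fluticasone", "salmeterol",
            "montelukast", "theophylline", "prednisolone", "ciclesonide"],
  "symptoms": ["wheezing", "coughing", "dyspnea", "tightness",
               "inflammation", "remodeling", "hyperresponsiveness",
               "breathlessness", "exacerbation", "obstruction",
               "hypoxemia", "tachypnea"],
  "comorbidities": ["allergies", "obesity", "depression", "COPD", "GERD",
                    "rhinitis", "sinusitis", "anxiety", "bronchiectasis",
                    "eczema", "apnea", "polyposis"],
  "modifiers": ["severe", "mild", "chronic", "acute", "inhaled", "oral",
                "persistent", "nocturnal", "refractory", "pediatric",
                "allergic", "eosinophilic"]
}
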