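species,term,source,provisional
"Phoenix dactylifera","poisoning treatment","B23",FALSE
"Phoenix dactylifera","endo- and ectoparasitic","B24",FALSE
"Phoenix dactylifera","eye diseases including conjunctivitis","B25",FALSE
"Phoenix dactylifera","wounds","B25",FALSE
"Calotropis procera","mange","B26",FALSE
"Calotropis procera","musculoskeletal disorders","B27",FALSE
"Calotropis procera","dermatological disorders","B27",FALSE
"Achillea eriophora","bloating","B28",FALSE
"Ferula assa-foetida","intestinal worm elimination","Abbasnia et al.",FALSE
"Ferula assa-foetida","increasing milk production","Abbasnia et al.",FALSE
"Eruca sativa","tick infestation","B29",FALSE
"Capparis spinosa","joint pain killer","B13;B28",FALSE
"Capparis spinosa","respiratory problems","B24",FALSE
"Capparis spinosa","ulcer","B30",FALSE
"Capparis spinosa","dysentery","B30",FALSE
"Capparis spinosa","sore eyes","B30",FALSE
"Capparis spinosa","toothache","B30",FALSE
"Glycyrrhiza glabra","diarrhea","B31",FALSE
"Glycyrrhiza glabra","dislocations and bruises","B28",FALSE
"Glycyrrhiza glabra","gastritis","B28",FALSE
"Glycyrrhiza glabra","gastrointestinal diseases","B13",FALSE
"Glycyrrhiza glabra","otitis","B13",FALSE
"Glycyrrhiza glabra","stomach swelling","B12",FALSE
"Glycyrrhiza glabra","cough","B30",FALSE
"Glycyrrhiza glabra","bronchitis","B30",FALSE
"Glycyrrhiza glabra","toothache","B30",FALSE
"Glycyrrhiza glabra","enteritis","B32",FALSE
"Glycyrrhiza glabra","arthritis","B32",FALSE
"Glycyrrhiza glabra","endo- and ectoparasitic","B24",FALSE
"Trigonella foenum-graecum","diarrhea","B31",FALSE
"Trigonella foenum-graecum","mastitis","B31",FALSE
"Trigonella foenum-graecum","endo- and ectoparasitic","B24",FALSE
"Trigonella foenum-graecum","wound","B30",FALSE
"Trigonella foenum-graecum","colic","B30",FALSE
"Trigonella foenum-graecum","paralysis","B30",FALSE
"Trigonella foenum-graecum","jaundice","B30",FALSE
"Trigonella foenum-graecum","gallbladder disorders","B33",FALSE
"Trigonella foenum-graecum","poisoning","B33",FALSE
"Trigonella foenum-graecum","increasing lactation","B33",FALSE
"Trigonella foenum-graecum","uterus prolapse","B34",FALSE
"Teucrium polium","gastrointestinal diseases","B13;B28;B31",FALSE
"Teucrium polium","constipation","B30",FALSE
"Teucrium polium","cough","B30",FALSE
"Teucrium polium","asthma","B30",FALSE
"Teucrium polium","vomiting","B35",FALSE
"Teucrium polium","abdominal pain","B35",FALSE
"Teucrium polium","wounds","B35",FALSE
"Sesamum indicum","diarrhea","B29",FALSE
"Triticum aestivum","mastitis","B23",FALSE
"Triticum aestivum","enhancement of lactation","B31",FALSE
"Triticum aestivum","bloating","B12",FALSE
"Triticum aestivum","infection","B12",FALSE
"Triticum aestivum","indigestion","B12",FALSE
"Triticum aestivum","anemia","B12",FALSE
"Triticum aestivum","rickets","B12",FALSE
"Triticum aestivum","scabies","B12",FALSE
"Ziziphus nummularia","preventing hair loss","B28",FALSE
"Ziziphus nummularia","mild skin disorders","B28",FALSE
"Ziziphus spina-christi","preventing hair loss","B28",TRUE
"Ziziphus spina-christi","mild skin disorders","B28",TRUE
"Coffea arabica","wound","B30",FALSE
"Coffea arabica","cough","B30",FALSE
"Coffea arabica","sore eyes","B30",FALSE
"Coffea arabica","jaundice","B30",FALSE
"Coffea arabica","urinary problems","B25",FALSE
"Coffea arabica","sunburn","B25",FALSE
"Camellia sinensis","stomach ache","B7;B33",FALSE
"Camellia sinensis","endo- and ectoparasitic","B24",FALSE
"Camellia sinensis","flatulence","B30",FALSE
"Camellia sinensis","ulcer","B30",FALSE
"Camellia sinensis","constipation","B30",FALSE
"Camellia sinensis","flu","B30",FALSE
"Camellia sinensis","fever","B4",FALSE
"Curcuma longa","mastitis","B4",FALSE
"Curcuma longa","wound treatment","B4",FALSE
"Curcuma longa","joint pain","B4",FALSE
"Curcuma longa","jaundice","B30",FALSE
"Curcuma longa","enteritis","B30",FALSE
"Curcuma longa","swellings","B30",FALSE
"Curcuma longa","caprine arthritis encephalitis palliative","B36",FALSE
"Curcuma longa","proud flesh","B36",FALSE
"Curcuma longa","infectious wound","B29",FALSE
"Prunus eburnea","leishmaniasis","B23;B12;B13",FALSE
"Prunus eburnea","oestrus ovis larvae","B23;B12;B13",FALSE
"Ephedra pachyclada","respiratory problems","synthetic",TRUE
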