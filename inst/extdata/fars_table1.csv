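species,family,voucher,usage,plant_part,route,reported_usage,label,provisional
"Phoenix dactylifera","Arecaceae","3649","Treatment of grass tetany in livestock","Fruit","oral","Poisoning treatment; endo- and ectoparasitic; eye diseases including conjunctivitis; wounds","divergent",TRUE
"Calotropis procera","Asclepiadaceae","3324","Infected wounds","Resin","topical","Mange; musculoskeletal disorders; dermatological disorders","corroborated",TRUE
"Achillea eriophora","Asteraceae","2008","Diarrhea","Aerial parts","oral","Bloating","corroborated",TRUE
"Matricaria aurea","Asteraceae","15063","Reduction in pain and swelling in the postpartum animal's udder and wound healing","Aerial parts","vapor","_","novel",FALSE
"Ferula assa-foetida","Apiaceae","16371","Treatment for cough, parasites, and muscle stiffness, or when a nursing animal's milk is discontinued","Root","oral","Intestinal worm elimination and increasing milk production","corroborated",FALSE
"Periploca graeca","Apocynaceae","7823","Animal bite; livestock fracture","Aerial parts","topical","_","novel",FALSE
"Berberis sp.","Berberidaceae","","Muscle pain","Root","oral","_","novel",FALSE
"Tecomella undulata","Bignoniaceae","22400","Animal bite caused by lizard","Bark/resin","topical","_","novel",FALSE
"Eruca sativa","Brassicaceae","9776","Scabies disease in camels","Seed","topical","Tick infestation","corroborated",TRUE
"Capparis spinosa","Capparidaceae","1393","Animal fractures; eliminating worms and external wound infections in animals and uterine wounds","Aerial parts","topical","Joint pain killer; respiratory problems; ulcer; dysentery; sore eyes; toothache","divergent",FALSE
"Astragalus fasciculifolius","Fabaceae","1736","Fractures; weaning livestock","Bark/root; resin","topical","_","novel",FALSE
"Glycyrrhiza glabra","Fabaceae","15485","Fractures","Root/aerial part","oral","Diarrhea; relieving and reducing pain and swelling in dislocations and bruises; gastritis; gastrointestinal diseases; otitis; stomach swelling; cough; bronchitis; toothache; enteritis; arthritis; endo- and ectoparasitic","corroborated",TRUE
"Trigonella foenum-graecum","Fabaceae","10267","Severe diarrhea, cough, and muscle cramps","Seed","oral","Diarrhea; mastitis; endo- and ectoparasitic; wound; colic; paralysis; jaundice; gallbladder disorders; poisoning; increasing lactation; uterus prolapse","corroborated",TRUE
"Otostegia persica","Lamiaceae","14093","Fractures","Stem","topical","_","novel",FALSE
"Teucrium polium","Lamiaceae","14428","Animal bites","Aerial parts","topical","Gastrointestinal diseases; constipation; cough; asthma; vomiting; abdominal pain; wounds","divergent",TRUE
"Zataria multiflora","Lamiaceae","16168","Diarrhea","Leaves","oral","_","novel",FALSE
"Ficus johannis","Moraceae","","Joint pain; fracture","Fruit; leaves","oral","_","novel",FALSE
"Sesamum indicum","Pedaliaceae","","Muscle stiffness and pain","Seed","nasal","Diarrhea","divergent",TRUE
"Triticum aestivum","Poaceae","","Diarrhea","Seed","oral","Mastitis; enhancement of lactation; bloating; infection; indigestion; anemia; rickets; scabies","corroborated",TRUE
"Ziziphus nummularia","Rhamnaceae","4776","Poisoning","Root","oral","Preventing hair loss; mild skin disorders","divergent",TRUE
"Ziziphus spina-christi","Rhamnaceae","3431","Diarrhea and strengthening the intestinal villi","Leaves","oral","Preventing hair loss; mild skin disorders","divergent",TRUE
"Crataegus aronia","Rosaceae","14186","Urinary retention","Fruit","oral","_","novel",FALSE
"Prunus amygdalus","Rosaceae","","Fractures","Fruit","topical","_","novel",FALSE
"Prunus eburnea","Rosaceae","8054","Joint pain, infections, and intestinal worms; boosting the overall health and increasing milk production","Whole plant; root","oral","Leishmaniasis; Oestrus ovis larvae","corroborated",TRUE
"Amygdalus scoparia","Rosaceae","14059","Fractures","Fruit","topical","_","novel",FALSE
"Coffea arabica","Rubiaceae","","Diarrhea","Seed","oral","Wound; cough; sore eyes; jaundice; urinary problems; sunburn","divergent",TRUE
"Haplophyllum laristanicum","Rutaceae","25000","Diarrhea in livestock during winter; muscle cramps","Aerial parts","oral","_","novel",FALSE
"Citrus aurantiifolia","Rutaceae","","Fever","Fruit","oral","_","novel",FALSE
"Camellia sinensis","Theaceae","","Grass tetany in livestock","Leaves","oral","Stomach ache; endo- and ectoparasitic; flatulence; ulcer; constipation; flu; fever","divergent",TRUE
"Curcuma longa","Zingiberaceae","","Fractures, infected wound","Rhizome","topical","Mastitis; wound treatment; joint pain; jaundice; enteritis; swellings; caprine arthritis encephalitis palliative; proud flesh; infectious wound","corroborated",TRUE
"Ephedra pachyclada","Ephedraceae","5827","Component of the Tengrez complex remedy: preventing miscarriage, weight gain, increasing milk production, treating parasitic infections, and nosebleed","Aerial part","oral","Respiratory problems","divergent",TRUE
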