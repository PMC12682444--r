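term,category
"animal bite","animal bite"
"animal bites","animal bite"
"digestive","digestive"
"diarrhea","digestive"
"dysentery","digestive"
"bloating","digestive"
"intestinal worm elimination","digestive"
"intestinal worms","digestive"
"ulcer","digestive"
"gastritis","digestive"
"gastrointestinal diseases","digestive"
"stomach swelling","digestive"
"stomach ache","digestive"
"colic","digestive"
"abdominal pain","digestive"
"vomiting","digestive"
"constipation","digestive"
"flatulence","digestive"
"indigestion","digestive"
"enteritis","digestive"
"poisoning","digestive"
"poisoning treatment","digestive"
"endo- and ectoparasitic","digestive"
"oestrus ovis larvae","digestive"
"epistaxis","epistaxis"
"nosebleed","epistaxis"
"nosebleeding","epistaxis"
"fever","fever"
"fractures","fractures"
"fracture","fractures"
"dislocations and bruises","fractures"
"grass tetany","grass tetany"
"increasing milk production","increasing milk production"
"increasing lactation","increasing milk production"
"enhancement of lactation","increasing milk production"
"infected wound","infected wound"
"infected wounds","infected wound"
"wound","infected wound"
"wounds","infected wound"
"wound treatment","infected wound"
"infectious wound","infected wound"
"infection","infected wound"
"dermatological disorders","infected wound"
"lambing","lambing"
"uterine wounds","lambing"
"uterus prolapse","lambing"
"muscle and joint pain","muscle and joint pain"
"joint pain","muscle and joint pain"
"joint pain killer","muscle and joint pain"
"muscle pain","muscle and joint pain"
"muscular pain","muscle and joint pain"
"muscle cramps","muscle and joint pain"
"muscle stiffness","muscle and joint pain"
"musculoskeletal disorders","muscle and joint pain"
"arthritis","muscle and joint pain"
"respiratory","respiratory"
"respiratory problems","respiratory"
"cough","respiratory"
"bronchitis","respiratory"
"asthma","respiratory"
"flu","respiratory"
"scabies","scabies"
"mange","scabies"
"tick infestation","scabies"
"mild skin disorders","scabies"
"udder problems","udder problems"
"mastitis","udder problems"
"urinary retention","urinary retention"
"urinary problems","urinary retention"
"weaning","weaning"
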