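ailment,species,fl
animal bite,"Tecomella undulata (Sm.) Seem.",100
animal bite,"Teucrium polium L. (C)",100
animal bite,"Periploca graeca L.",83.33
digestive,"Achillea eriophora DC.",100
digestive,"Amygdalus lycioides Spach",40
digestive,"Coffea arabica L.",100
digestive,"Ephedra pachyclada Boiss.",100
digestive,"Haplophyllum laristanicum C.C.Towns.",75
digestive,"Ferula assa-foetida Boiss.",81.03
digestive,"Trigonella foenum-graecum L.",50
digestive,"Triticum aestivum L.",33.33
digestive,"Zataria multiflora Boiss.",100
digestive,"Ziziphus nummularia (Burm.f.) Wight. & Arn.",100
digestive,"Ziziphus spina-christi (L.) Desf.",100
epistaxis,"A. lycioides Spach",20
epistaxis,"E. pachyclada Boiss.",100
epistaxis,"Ferula assa-foetida Boiss.",1.72
fever,"Citrus × aurantiifolia (Christm.) Swingle",100
fractures,"Amygdalus scoparia Spach",100
fractures,"Astragalus fasciculifolius Boiss.",92.86
fractures,"Capparis spinosa L.",40
fractures,"Curcuma longa L.",100
fractures,"Ferula assa-foetida Boiss.",3.45
fractures,"Glycyrrhiza glabra L.",100
fractures,"Otostegia persica (Burm.) Boiss.",100
fractures,"Prunus amygdalus Batsch",100
fractures,"Triticum aestivum L.",66.67
fractures,"P. graeca L.",16.67
grass tetany,"Camellia sinensis (L.) Kuntze",100
grass tetany,"Ferula assa-foetida Boiss.",3.45
grass tetany,"Phoenix dactylifera L.",100
increasing milk production,"A. lycioides Spach",40
increasing milk production,"E. pachyclada Boiss.",100
increasing milk production,"Ferula assa-foetida Boiss.",1.72
infected wound,"A. fasciculifolius Boiss.",14.29
infected wound,"Calotropis procera (Aiton) W.T.Aiton",100
infected wound,"C. spinosa L.",60
infected wound,"Curcuma longa L.",100
infected wound,"Ferula assa-foetida Boiss.",5.17
lambing,"A. lycioides Spach",20
lambing,"Matricaria aurea (Loefl.) Sch.Bip.",100
lambing,"C. spinosa L.",20
muscle and joint pain,"A. lycioides Spach",80
muscle and joint pain,"Berberis sp.",100
muscle and joint pain,"E. pachyclada Boiss.",100
muscle and joint pain,"H. laristanicum C.C.Towns.",25
muscle and joint pain,"Ferula assa-foetida Boiss.",50
muscle and joint pain,"Ficus johannis Boiss.",100
muscle and joint pain,"O. persica (Burm.) Boiss.",20
muscle and joint pain,"Sesamum indicum L.",100
muscle and joint pain,"Trigonella foenum-graecum L.",50
respiratory,"Ferula assa-foetida Boiss.",3.45
respiratory,"Trigonella foenum-graecum L.",100
scabies,"Eruca sativa Miller",100
udder problems,"Matricaria aurea (Loefl.) Sch.Bip.",100
udder problems,"Ferula assa-foetida Boiss.",1.72
udder problems,"T. undulata (Sm.) Seem.",100
urinary retention,"Crataegus aronia (L.) Steud.",100
weaning,"A. fasciculifolius Boiss.",7.14
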