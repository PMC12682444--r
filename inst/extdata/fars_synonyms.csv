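variant,canonical,ambiguous
"Achillea eriophora DC.","Achillea eriophora",FALSE
"Prunus eburnea (Spach) Aitch.","Prunus eburnea",FALSE
"Amygdalus lycioides Spach","Prunus eburnea",FALSE
"A. lycioides Spach","Prunus eburnea",FALSE
"Amygdalus lycioides","Prunus eburnea",FALSE
"Amygdalus scoparia Spach","Amygdalus scoparia",FALSE
"Prunus scoparia (Spach) C.K. Schneid.","Amygdalus scoparia",FALSE
"Prunus scoparia","Amygdalus scoparia",FALSE
"Matricaria aurea (Loefl.) Sch.Bip.","Matricaria aurea",FALSE
"Astragalus fasciculifolius Boiss.","Astragalus fasciculifolius",FALSE
"A. fasciculifolius Boiss.","Astragalus fasciculifolius",FALSE
"Berberis sp.","Berberis sp.",FALSE
"Calotropis procera (Aiton) W.T.Aiton","Calotropis procera",FALSE
"Camellia sinensis (L.)","Camellia sinensis",FALSE
"Camellia sinensis (L.) Kuntze","Camellia sinensis",FALSE
"Capparis spinosa L.","Capparis spinosa",FALSE
"C. spinosa L.","Capparis spinosa",FALSE
"Citrus × aurantiifolia (Christm.) Swingle","Citrus aurantiifolia",FALSE
"Coffea arabica L.","Coffea arabica",FALSE
"Crataegus aronia (L.) Steud.","Crataegus aronia",FALSE
"Curcuma longa L.","Curcuma longa",FALSE
"Ephedra pachyclada Boiss.","Ephedra pachyclada",FALSE
"E. pachyclada Boiss.","Ephedra pachyclada",FALSE
"Eruca sativa Miller","Eruca sativa",FALSE
"Haplophyllum laristanicum C.C.Towns.","Haplophyllum laristanicum",FALSE
"H. laristanicum C.C.Towns.","Haplophyllum laristanicum",FALSE
"Ferula assa-foetida Boiss.","Ferula assa-foetida",FALSE
"Ficus johannis Boiss.","Ficus johannis",FALSE
"Glycyrrhiza glabra L.","Glycyrrhiza glabra",FALSE
"Otostegia persica (Burm.) Boiss.","Otostegia persica",FALSE
"Otostegia persica (Burm.f.) Boiss.","Otostegia persica",FALSE
"O. persica (Burm.) Boiss.","Otostegia persica",FALSE
"Periploca graeca L.","Periploca graeca",FALSE
"P. graeca L.","Periploca graeca",FALSE
"Phoenix dactylifera L.","Phoenix dactylifera",FALSE
"Prunus amygdalus Batsch","Prunus amygdalus",FALSE
"Sesamum indicum L.","Sesamum indicum",FALSE
"Tecomella undulata (Sm.) Seem.","Tecomella undulata",FALSE
"T. undulata (Sm.) Seem.","Tecomella undulata",FALSE
"Teucrium polium L. (C)","Teucrium polium",FALSE
"Trigonella foenum-graecum L.","Trigonella foenum-graecum",FALSE
"Triticum aestivum L.","Triticum aestivum",FALSE
"Zataria multiflora Boiss.","Zataria multiflora",FALSE
"Ziziphus nummularia (Burm.f.) Wight. & Arn.","Ziziphus nummularia",FALSE
"Ziziphus spina-christi (L.) Desf.","Ziziphus spina-christi",FALSE
"Ziziphus sp.","Ziziphus nummularia",TRUE
"Ziziphus sp.","Ziziphus spina-christi",TRUE
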