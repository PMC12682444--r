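ailment,species,cv
animal bite,"Periploca graeca L.",1.67
animal bite,"Tecomella undulata (Sm.) Seem.",1
digestive,"Ferula assa-foetida Boiss.",4.27
digestive,"Ziziphus sp.",0.45
fractures,"Astragalus fasciculifolius Boiss.",1.3
fractures,"Otostegia persica (Burm.) Boiss.",0.5
grass tetany,"Camellia sinensis (L.) Kuntze",0.67
grass tetany,"Ferula assa-foetida Boiss.",0.67
grass tetany,"Phoenix dactylifera L.",0.67
increasing milk production,"Amygdalus lycioides Spach",0.66
infected wound,"Capparis spinosa L.",0.6
infected wound,"Ferula assa-foetida Boiss.",0.6
muscle and joint pain,"Ferula assa-foetida Boiss.",3.22
muscle and joint pain,"A. lycioides Spach",0.44
respiratory,"Ferula assa-foetida Boiss.",1
respiratory,"Trigonella foenum-graecum L.",1
scabies,"Eruca sativa Miller",2
udder problems,"T. undulata (Sm.) Seem",1
urinary retention,"Crataegus aronia (L.) Steud.",2
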