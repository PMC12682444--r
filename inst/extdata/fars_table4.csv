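ailment,nur,ntaxa,icf
animal bite,9,5,0.5
digestive,70,11,0.86
epistaxis,3,3,0
fever,1,1,0
fractures,30,10,0.69
grass tetany,6,3,0.6
increasing milk production,4,3,0.33
infected wound,11,5,0.6
lambing,3,3,0
muscle and joint pain,40,9,0.79
respiratory,4,2,0.67
scabies,2,1,1
udder problems,5,3,0.5
urinary retention,1,1,0
weaning,1,1,0
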