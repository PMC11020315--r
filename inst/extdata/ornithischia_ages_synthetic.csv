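taxon,fad,lad
Silesaurus,230,225
Lesothosaurus,200,190
Scelidosaurus,196,189
Hungarosaurus,86,84
Pinacosaurus,84,75
Edmontonia,76,69
Heterodontosaurus,200,190
Yinlong,160,157
Liaoceratops,126,122
Psittacosaurus,125,101
Hypsilophodon,130,125
Jeholosaurus,125,122
Changchunsaurus,112,100
Thescelosaurus,68,66
Tenontosaurus,115,108
Mochlodon,84,72
Iguanodon,126,122
Edmontosaurus,73,66
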