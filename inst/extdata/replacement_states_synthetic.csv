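taxon,state
Silesaurus,one_generation
Lesothosaurus,one_generation
Scelidosaurus,one_generation
Hungarosaurus,one_generation
Pinacosaurus,two_generations
Edmontonia,one_generation
Heterodontosaurus,one_generation
Yinlong,two_generations
Liaoceratops,two_generations
Psittacosaurus,two_generations
Hypsilophodon,one_generation
Jeholosaurus,two_generations
Changchunsaurus,two_generations
Thescelosaurus,one_generation
Tenontosaurus,two_generations
Mochlodon,one_generation
Iguanodon,two_generations
Edmontosaurus,three_plus
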