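(Silesaurus,(Lesothosaurus,((Scelidosaurus,(Hungarosaurus,(Pinacosaurus,Edmontonia))),((Heterodontosaurus,(Yinlong,(Liaoceratops,Psittacosaurus))),(Hypsilophodon,((Jeholosaurus,Changchunsaurus),(Thescelosaurus,(Tenontosaurus,(Mochlodon,(Iguanodon,Edmontosaurus))))))))));
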