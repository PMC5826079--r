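(Dehalococcoides,(((Herpetosiphon,Kallotenue),(Chloroflexus,(Kouleothrix,Roseiflexus))),((Roseilinea,JP3_7),(Anaerolineae,((JP3_13,(CP1_1M,CP2_2F)),((CP2_20G,JP1_20),(JP1_16,(JP1_8,CP2_42A))))))));
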