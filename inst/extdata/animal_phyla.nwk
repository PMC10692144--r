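(Porifera,(Ctenophora,(Placozoa,(Cnidaria,(Xenacoelomorpha,((Echinodermata,Chordata),((Platyhelminthes,(Rotifera,(Mollusca,(Annelida,(Nemertea,Brachiopoda))))),(Nematoda,(Tardigrada,Arthropoda)))))))));
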