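label	group
Chlorophyta	autotroph
Cryptophyta	mixotroph
Ciliophora	phagotroph
Perkinsea	parasite
Oomycota	osmotroph
Dinophyceae	mixotroph
Chrysophyceae	mixotroph
Cercozoa	phagotroph
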