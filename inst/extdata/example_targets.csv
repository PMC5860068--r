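name,formula,adducts
d-tryptophan,C11H12N2O2,[M+H];[M+Na];[M-H]
glucose,C6H12O6,[M+Na];[M-H]
epinephrine,C9H13NO3,[M-H]
choline,C5H14NO,[M+]
taurine,C2H7NO3S,[M+H]
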