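# Toy nonbonded parameter set for synthetic-trajectory work.
# sigma in nm, epsilon in kJ/mol.  Na/Cl rows carry the amber ion values
# used by the emulated study.
type sigma epsilon
C  0.340 0.360
O  0.296 0.879
N  0.325 0.711
H  0.106 0.0657
Na 0.244 0.366
Cl 0.448 0.149
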