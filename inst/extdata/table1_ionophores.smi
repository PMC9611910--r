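# Four diphenylphosphoryl acetamide candidate ionophores (substance 2 linker
# reconstructed as pentane-1,5-diyl analogue; see table1_ionophores()).
CCCCCCCCN(CCCCN(CCCCCCCC)CC(=O)CP(=O)(c1ccccc1)c1ccccc1)CC(=O)CP(=O)(c1ccccc1)c1ccccc1 substance1
CCCCCCCCN(CCCCCN(CCCCCCCC)CC(=O)CP(=O)(c1ccccc1)c1ccccc1)CC(=O)CP(=O)(c1ccccc1)c1ccccc1 substance2
CCCCCCCCN(CCCCCCN(CCCCCCCC)CC(=O)CP(=O)(c1ccccc1)c1ccccc1)CC(=O)CP(=O)(c1ccccc1)c1ccccc1 substance3
O=C(CP(=O)(c1ccccc1)c1ccccc1)N1CCN(C(=O)CP(=O)(c2ccccc2)c2ccccc2)CC1 substance4
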