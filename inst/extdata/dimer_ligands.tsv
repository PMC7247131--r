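# Obligate dimer ligands: when every member protein is encoded in one
# operon, the members collapse to the joint ligand name.
joint	members
S6:S18	S6,S18
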