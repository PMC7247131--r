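# R-protein ligands previously established for r-leaders (experimentally
# verified or with a predicted alignment). Best-effort transcription from the
# r-leader literature; user-replaceable. Dimer ligands use joint names.
ligand	provenance
L1	literature
L4	literature
L10	literature
L13	literature
L19	literature
L20	literature
L21	literature
L25	literature
L35	literature
S1	literature
S2	literature
S4	literature
S6:S18	literature
S7	literature
S8	literature
S10	literature
S15	literature
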