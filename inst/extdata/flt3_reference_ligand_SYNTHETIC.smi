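# SYNTHETIC STAND-IN reference ligand.
# The worked example compares the designed candidate against a ChEMBL-curated
# FLT3-interacting ligand.  That record must be fetched from ChEMBL by the
# user; this file ships sorafenib (a public, well-known FLT3-active kinase
# inhibitor) as a clearly-labelled stand-in so the example runs offline.
CNC(=O)c1cc(Oc2ccc(NC(=O)Nc3ccc(Cl)c(C(F)(F)F)c3)cc2)ccn1	sorafenib_standin
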