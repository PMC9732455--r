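# Designed candidate of the worked example:
# 4-(4-tert-butylbenzamido)-2-(piperidin-3-ylamino)benzamide
NC(=O)c1c(NC2CCCNC2)cc(NC(=O)c3ccc(C(C)(C)C)cc3)cc1	design_candidate
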