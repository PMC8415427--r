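raw_term	canonical_tissue
blood	blood
whole blood	blood
peripheral blood	blood
brain	brain
cerebral cortex	brain
heart	heart
cardiac muscle	heart
kidney	kidney
renal cortex	kidney
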