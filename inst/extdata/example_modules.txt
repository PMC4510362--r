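ENTRY       M00801  Pathway
NAME        toy two-step pathway (phosphofructokinase step, aldolase step)
DEFINITION  (K00850,K16370,K00918) K01624
///
ENTRY       M00802  Complex
NAME        toy four-subunit oxidoreductase complex
DEFINITION  K00174+K00175+K00176+K00177
///
ENTRY       M00803  Pathway
NAME        toy pathway with an optional subunit and a grouped step
DEFINITION  K02025-K02026 (K00001 K00002) K00003
///
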