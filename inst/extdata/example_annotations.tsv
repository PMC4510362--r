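# toy genome annotation: gene_id<TAB>ko_id
toy_g0001	K00918
toy_g0002	K01624
toy_g0003	K00174
toy_g0004	K00175
toy_g0005	K02025
toy_g0006	K00001
toy_g0007	K00002
toy_g0008	K00003
toy_g0009	K00918
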