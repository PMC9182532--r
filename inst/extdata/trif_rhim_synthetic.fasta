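>trif_rhim_synthetic synthetic 112-residue RHIM construct, full-length positions 601-712 (offset 601); VQLG tetrad at 663-666
SELVMQKMHCAKVRNNGICRYDSWMHYQHIVSNYYLHPYIAWCNYIPRWSNQQPLIIHHAQ
MVQLGTREFGYCGIKSPELNVASYSSHPEMGVTSCGKPPATNLPSYIHNIT
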