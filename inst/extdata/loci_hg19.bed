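chrX	66764465	66950461	AR
chr10	89623194	89728532	PTEN
chr21	39739182	42903043	TMPRSS2_ERG
chr8	45600000	146364022	8q
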