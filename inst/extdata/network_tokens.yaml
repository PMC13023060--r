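# Mapping from parcellation label tokens to short network codes.
# Edit or replace to support other label dialects.
Vis: VN
SomMot: SMN
DorsAttn: DAN
SalVentAttn: VAN
Limbic: LN
Cont: CN
Default: DMN
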