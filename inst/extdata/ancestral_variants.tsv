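hgvs
m.750A>G
m.2706A>G
m.263A>G
m.15326A>G
m.9769delT
m.12272delA
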