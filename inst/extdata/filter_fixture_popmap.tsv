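sample_id	population
s01	P1
s02	P1
s03	P1
s04	P1
s05	P1
s06	P1
s07	P1
s08	P1
s09	P1
s10	P1
s11	P2
s12	P2
s13	P2
s14	P2
s15	P2
s16	P2
s17	P2
s18	P2
s19	P2
s20	P2
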