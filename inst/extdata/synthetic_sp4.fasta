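>sp4_h1
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
>sp4_h2
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGAGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
>sp4_h3
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGAGGGGGGGGGGAGGGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGAAGGGGGGGGGGGGGGGGGAAGGGGGGGGGGGGGGAGGGGAGGGGGGGGGGG
>sp4_h4
GAGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAAGAGGAGGAGGGGAGGGGGGGGGGGGGGGAGGGGAGGAGGGGGGAGG
GGGGGGGGGGGGGGGGGGAAGGGGGGGGGGGGGGGGGAAGGGGGAGGGGGGGGAGGGGAGGGGGGGGGAG
>sp4_h5
GAGGGGGGGGGAGGGGGGGGGGGGGGGGAGGGAAGAGGAAGAGGAGAGGGGGGGGGAGAGGGAAGGGAGGAGAGGGGAGA
GGGGAGGGGGAGAGGGGGAAGGGGGGGGAGGGGAGGGAAGGGAGAGGGGAGAGAAGGGAGGAGAGAGGAG
>sp4_h6
GAAGGAGGGGGAGAGGGGGGGGAGGGGGAAGGAAGAAGAAGAGGAGAAGGGGGAAAAGAGGGAAGGGAGGAAAGGGGAGA
AGGGAGGGGAAGAGAGGGAAGGGGGGGGAAGGGAGAGAAGGGAGAGAGGAAAGAAGGGAGGAGAAAGGAA
>sp4_h7
GAAGGAGGGAAAGAAGAAAGAAAGGAAGAAGAAAGAAGAAAAGAAGAAGGGGGAAAAGAGGGAAGGGAAGAAAGGGGAGA
AAAGAGGGGAAAAGAGGGAAGAGAGGGAAAAGGAGAAAAGGGAGAGAGGAAAAAAAGAAGAAAAAAAAAA
>sp4_h8
AAAAGAGGGAAAAAAGAAAAAAAAGAAAAAGAAAGAAGAAAAAAAAAAGAGGAAAAAAAGAAAAAGGAAGAAAGGGAAAA
AAAGAGGGGAAAAAAGAGAAAAAAAGAAAAAGAAGAAAAGAGAGAGAAAAAAAAAAGAAAAAAAAAAAAA
>sp4_h9
AAAAAAGAGAAAAAAGAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGGAAAAAAAGAAAAAGGAAGAAAAGGAAAA
AAAAAAGGGAAAAAAGAGAAAAAAAAAAAAAGAAGAAAAGAGAGAAAAAAAAAAAAGAAAAAAAAAAAAA
>sp4_h10
AAAAAAAAGAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGGAAAAAAAAAAAAAAGAAAAAAAGGAAAA
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAAAAAAGAAAAAAAAAAAAA
>sp4_h11
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAAAAAAAAAAAAAAAAGGAAAA
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>sp4_h12
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAA
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
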