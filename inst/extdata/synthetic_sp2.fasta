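>sp2_h1
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
>sp2_h2
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
>sp2_h3
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGGGAGG
GAGGGGGGGGGGGGGGGGGGGGGGAGGGGAGGAGGGGGAGGGGGGGGGGGGGGGGGGAGGGGGGGGGGGG
>sp2_h4
GGGGGGGGGGGAGGAGGAGGGGGGGGGGGGGGGGGAAAGGAGGAGGGGGGGAGGGGGGAAGGGGGGGGGGGGGGGGGAGG
GAGGGGGGGGAGGGGGGGGGGGGGAGAGGAGGAAGGGGAGGAGGGGGGGGGGGGGGGAGGGGGGGGGGGG
>sp2_h5
GGGGGAGGGGGAGGAGGAGGGGAGGGGGAGGGGGGAAAGAAGGAGGGGGGGAGGGGGGAAGGGGGGGGGGGGGAGGGAGG
GAGGGAGGGGAGGGGGGGGGGGGGAGAGGAGAAAGAAGAGGAGAGGGGGGGGGGGGAAAGGGGAGGGAAG
>sp2_h6
GGGGGAAGGAGAAGAAAAGGGGAGGAGGAGGAGGAAAAAAAGGAGAGGGAGAGGGGAGAAAGGAAGGGGAGGGAGGGAGG
GAGGGAAGGGAGGAAGGGGAGGAGAGAGGAGAAAGAAAAGGAGAAGGGAGGAAAGGAAAAGGGAGAAAAG
>sp2_h7
AGGAAAAGAAAAAGAAAAGGGGAGGAGGAGGAAGAAAAAAAGGAGAGAAAGAGGAAAAAAAAAAAGGAAAGAGAGAGAGG
GAAGGAAGGGAGGAAGAGAAGAAGAAAGGAGAAAGAAAAGGAGAAGGGAAGAAAGGAAAAGGGAAAAAAG
>sp2_h8
AGGAAAAAAAAAAAAAAAAGAAAAGAGGAGGAAGAAAAAAAGAAGAAAAAGAGAAAAAAAAAAAAAGAAAGAGAGAGAAA
GAAAGAAGGAAGGAAGAGAAAAAGAAAAAAGAAAAAAAAGGAGAAAAAAAGAAAGAAAAAGGGAAAAAAG
>sp2_h9
AGAAAAAAAAAAAAAAAAAGAAAAAAGAAAAAAAAAAAAAAGAAAAAAAAGAAAAAAAAAAAAAAAGAAAGAAAAAGAAA
AAAAAAAAGAAAGAAGAGAAAAAGAAAAAAAAAAAAAAAAAAGAAAAAAAGAAAAAAAAAGAAAAAAAAA
>sp2_h10
AGAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAAAAAAA
AAAAAAAAAAAAAAAAAGAAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAGAAAAAAAAAAAAAAAAAAA
>sp2_h11
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAAAAAAA
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAGAAAAAAAAAAAAAAAAAAA
>sp2_h12
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAAAAAAA
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
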