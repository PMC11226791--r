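>sp6_h1
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
>sp6_h2
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GAGGGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGGGAGGGGGGGGGGGG
>sp6_h3
GGGGGGGGGGGGGGGGGGGGGGGGGGGGAGGAGGGGGGGGGGGGGGGGGGGGGGAGGAGGAGGGGGGGGGGGGGGGGGGG
GAGGGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGGGGGAGGGGGGGGGGGGGGAAGGAGGGGGGGGGGGG
>sp6_h4
AGGAAGGGGGGGGGGGGGGGGGGGGGGGAAGAGGGGGGAGAGGGGGGGGGGGGGAGGAGGAGGGGGAGGGGGGGGGGGGG
GAGGGAGGGAGGGGGGGAGGGGGGGGGGAGGGGGGAGGAGGGGAGGGGGGGGAAAGGAGGGGGGGGGGGG
>sp6_h5
AGGAAGGGGGGGGAGAAGAAGGAGGGAGAAGAGGGGGAAGAGGAGGGGGGGGGGAAGAGGAGGGGGAGGGGGGAGGGGGG
GAGGGAGGGAGGGGGAGAGGAGGGGGGAAAAGGAGAGGAGGGGAGGGGGGGGAAAGGAGAGGGGGGGGGG
>sp6_h6
AAAAAAAAGAGGGAGAAGAAGGAGGAAAAAGAGGGAAAAAAAGAAAAGGAAGGGAAAAGGAGGGGGAGGGAGGAGGAAAG
AAGGAAAGGAAGGGGAAAGGAGAGGAGAAAAGGAGAGAAGGAGAGGGGGGGGAAAAGAAAAGGGGGAGGG
>sp6_h7
AAAAAAAAAAGGGAAAAGAAAGAAGAAAAAGAAAGAAAAAAAGAAAAAAAAGGGAAAAGAAAAAAGAAAGAGGAAGAAAG
AAGGAAAGGAAGAGGAAAGGAGAAGAGAAAAGGAGAGAAGAAGAGAAAGGGGAAAAGAAAAGAGGGAGGG
>sp6_h8
AAAAAAAAAAAGAAAAAAAAAGAAGAAAAAGAAAAAAAAAAAAAAAAAAAAGAGAAAAGAAAAAAGAAAGAAGAAAAAAA
AAAGAAAAGAAGAAAAAAGAAAAAGAAAAAAGAAAAGAAGAAGAGAAAGGAGAAAAGAAAAGAGAAAGGG
>sp6_h9
AAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAAGAAAAAAAAAAGAAAAAAAAAA
AAAAAAAAGAAAAAAAAAGAAAAAGAAAAAAGAAAAAAAAAAGAGAAAGGAGAAAAAAAAAAAGAAAAAG
>sp6_h10
AAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAAAA
AAAAAAAAGAAAAAAAAAGAAAAAGAAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAAAAAAAAAAAAAA
>sp6_h11
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
AAAAAAAAGAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAAAAAAAAAAAAAA
>sp6_h12
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
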