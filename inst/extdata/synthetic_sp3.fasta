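>sp3_h1
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
>sp3_h2
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGGGGGAGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
>sp3_h3
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGGGGGAGAGGGGGAGGAAGAGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGAGGAGGGGGGGGGGAGGGGGGGGGGGGGGGGGGGGGGGGGGGAGGGGGGGGGGGGAGGG
>sp3_h4
GGGGGGGGGAGGGGGGGGGGGGGGGGGGGGGAGGGGGGAGGGGGAGAGGGGGAGGAAGAGGGGGGGGGGGGGGAGGGGGG
GGGGGGGGGGGAGGAGGGAGAGGAGAGGGGGGGGGGGGGGGGGGGGGGGGGGGAGGGGGGGGAGAGAGGA
>sp3_h5
AGAGGGAGGAAAGGGGGGAGGGGAGGGGGGGAGGGGGAAGGGGGAGAGGGGGAGGAAGAGGGGGGGGGGGGGGAGGAGGG
GAGGGAGGGGAAGGAGGAAGAGGAGAAGGGGGGAGGGGGGGGGGGGGAGGGGAAGGGGGGGGAAAGAGGA
>sp3_h6
AAAGGGAGGAAAGAGGGGAGAGGAGGGGAGGAAGGAGAAGGGGGAGAGGGGGAGGAAGAGGGGGGGGAGGGGGAGGAGAA
GAGGGAGGGGAAGGAAGAAGAGGAGAAAGAAGGAGGGGAGGGAGGGGAGGGGAAGGGAGGGGAAAGAAAA
>sp3_h7
AAAGGGAGAAAAGAGGGAAGAGAAGGGAAAGAAGGAGAAGGAAAAAAAGGAGAAGAAGAAGGAGGGGAGAGAAAGGAGAA
AAAGGAAGGGAAGGAAAAAGAAAAAAAAGAAGGAAGAGAAGGAGGGGAGGGAAAGAGAGGGGAAAGAAAA
>sp3_h8
AAAAAGAGAAAAGAGGGAAGAGAAGAAAAAAAAGGAAAAAGAAAAAAAAGAAAAAAAGAAAGAGGGGAGAGAAAGGAAAA
AAAGGAAGAAAAAGAAAAAAAAAAAAAAAAAGGAAAAAAAGAAAGGGAAGAAAAAAGAGGAGAAAGAAAA
>sp3_h9
AAAAAGAAAAAAAAGGGAAAAAAAGAAAAAAAAGAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAGAAAAGAAAGAAAAA
AAAAGAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAGAAAAGAAAGAAAAAAGAGGAAAAAAAAAA
>sp3_h10
AAAAAGAAAAAAAAAGAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAGAAAAA
AAAAGAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAGAAAAAAAAAAAAAAAAAAAA
>sp3_h11
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAAAAAAAAAAAAAAAAAA
>sp3_h12
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
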