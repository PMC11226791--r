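>sp7_h1
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
>sp7_h2
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
AGGGAGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
>sp7_h3
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGGGGGAGGGGGGGGGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGGGG
AGGGAGGGGGGGGGGGGGGGGAGGGGGGGAGGGGGAGGAGGGGGGGGGGGGGGAGGGGGGGGGGGGGGGG
>sp7_h4
AAGGAGGGGGGGGGGGGGGGGGGGGGGGGGGAAGGGGGAGGGGGGGGGGGGGGGGGGGGGAGGGGGGAGGGGGAGGGAGG
AGGGAGGGGGGGGGGGAGGGGAGGGGGGGAGGGGGAGGAGGGAGGGGGGGGGGAGGGGAGGGGGGGGGGG
>sp7_h5
AAGAAGGGGGGGGGAGGGGAGAGAGGAGGGGAAAGGGAAGGGGGGGGGGGGGGGGAGGGGAGGGAAGAGGAGGAGGAAGA
AGGGAAGGGGAGGGGGAGGGGAAGGGGAGAGAGGGAGGAGGGAGGGGGAGGGGAGAGAAGGGGGGGAGGG
>sp7_h6
AAGAAAGGGGGGGGAGAGAAGAAAGGAGGGGAAAGGGAAGGGGGGAGGGGGGGGAAAAGGAGGGAAGAAGAGGAAGAAGA
AGGGAAGGGAAGGGGGAGGAAAAGGGGAGAGAGGGAGGAGAGAGGGGGAGGGGAGAGAAAGGAGGGAAAG
>sp7_h7
AAGAAAGGAGGAGGAAAGAAGAAAAAAGGGGAAAGAAAAGGGAAAAAGGGGAAGAAAAGAAAAAAAAAAGAAGAAGAAGA
AGGAAAGGGAAGGGGAAGGAAAAGGAAAGAGAGAAAGGAGAGAGGGGGAGGAAAAAGAAAGGAGAAAAAG
>sp7_h8
AAGAAAAGAAGAGAAAAAAAGAAAAAAGAGGAAAGAAAAGGAAAAAAGGAGAAAAAAAGAAAAAAAAAAGAAGAAAAAGA
AGAAAAGGGAAGAAGAAAGAAAAAGAAAAAGAAAAAGGAAAGAAAGGAAGAAAAAAAAAAGGAAAAAAAA
>sp7_h9
AAGAAAAGAAAAAAAAAAAAGAAAAAAGAGAAAAGAAAAGAAAAAAAAAAGAAAAAAAAAAAAAAAAAAGAAAAAAAAAA
AAAAAAAAGAAGAAGAAAGAAAAAAAAAAAGAAAAAGAAAAGAAAAAAAGAAAAAAAAAAAAAAAAAAAA
>sp7_h10
AAAAAAAGAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAAAAAAAAAGAAAAAAAAAAAAAAAAAAGAAAAAAAAAA
AAAAAAAAGAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAAGAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>sp7_h11
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>sp7_h12
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
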