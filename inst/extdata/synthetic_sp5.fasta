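>sp5_h1
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
>sp5_h2
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGAGGGGGGGGAGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
>sp5_h3
GGGGGGGGGGGGGGGGGAAGGGGGAGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAAGGGGGG
GGGGGGGGGGGGGGGGGGGGAGGGGGGGGAGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
>sp5_h4
AGGGGGGGGGGGGGGGGAAGGGGAAGGGGAGGAGGGGGGGGGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGGAAGGGGGG
GGGGAGGGGAGAGGGGGAGGAGAGGGGGGAGGGGGAGGGGAGGGAGGGGGGAGAGGGGGAGGGGGGAGGG
>sp5_h5
AGGGGGAGGGGGGGGGGAAGGAGAAGGGGAGGAGGGGGGGGGGGGGGGGGAGGGAGGGGGGGGGGGAGGGAGAAAGAGGG
AGGGAGGGGAGAGGGGAAGGAGAGGAGGGAGGGGGAGGAGAGGGAAGGGGGAAAAGGGGAGGGGGGAGGG
>sp5_h6
AAGGGGAAGGAGGAAGGAAAGAGAAAAGGAAGAGGGAAAGGGGAAGGGGGAGGAAAGAAGGGGGGGAGGGAGAAAGAGGA
AGGAAAGAGAGAGGAGAAGGAGAGGAGGAAGGGAAAGGAAAGAAAAGGAGGAAAAGGAGAGGGGGGAGGG
>sp5_h7
AAAAAGAAGGAGGAAAGAAAGAAAAAAGAAAGAGAGAAAAAAGAAGGGAGAAGAAAAAAAAAGAGAAGGGAGAAAGAGGA
AGGAAAGAGAGAGGAAAAGGAAAGGAGAAAGGAAAAAAAAAGAAAAGGAGGAAAAAGAGAGGGGGGAAAG
>sp5_h8
AAAAAGAAGGAGGAAAGAAAGAAAAAAAAAAAAAAAAAAAAAGAAGAAAGAAAAAAAAAAAAGAGAAGGGAAAAAAAGAA
AAAAAAGAGAGAGGAAAAAAAAAGGAGAAAGAAAAAAAAAAGAAAAGAAGGAAAAAAAAAGGAAAGAAAA
>sp5_h9
AAAAAAAAAAAGAAAAAAAAGAAAAAAAAAAAAAAAAAAAAAGAAGAAAGAAAAAAAAAAAAAAAAAAAGAAAAAAAGAA
AAAAAAGAAAAAAAAAAAAAAAAAGAGAAAGAAAAAAAAAAAAAAAGAAGAAAAAAAAAAAGAAAGAAAA
>sp5_h10
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAAAAAAAAAAAAAGAAAAAAAAAA
AAAAAAGAAAAAAAAAAAAAAAAAGAGAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAAAAAGAAAAAAAA
>sp5_h11
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
AAAAAAGAAAAAAAAAAAAAAAAAGAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>sp5_h12
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
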