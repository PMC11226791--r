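>sp1_h1
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
>sp1_h2
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
>sp1_h3
GGGGGGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGAGGAGGGGGGGGGGGGGGGGGGGAGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGAGGGGGGGGGGGGGAGGGGAGGGGGGGGGGGGAGGGGGGGGGGGGGGGGGGGGG
>sp1_h4
GGGGGGGGGGGGGGGGAGAGGAGGGGGAGGGGGGGAAGAAGGGGGGGGGGGAGGGGGGAGAGGGGGGGGGAGGGGGGGGG
GGGGGGGGGGGGGGGGAGGGGGGGGGGGGGAGGGGAGGGGGGAGGGGGAGGGGGGAGGAGGGGGGGGGGG
>sp1_h5
GGGGGAGGGGGGAGGGAAAGGAGGGAGAGGGAGGAAAGAAGGGAGGGGGGGAGGGGGGAGAGAGGGGGGGAGGGGGGGGG
GGGGAGGGGGGGGGGGAGGGGGAGGGAGGGAGAAAAGGGGGAAGGGGGAGGAGGGAAGAGGAAGAGGGGA
>sp1_h6
GGAGAAGGGGGGAGAGAAAGGAAGGAAAGAGAGGAAAAAAGGGAAGAAGGGAGGAGGGAGAAAGGGGGAGAGGAGGAGGA
GGGGAGGGGGGGGGAGAAGAAAAGAGAAGGAAAAAAGGAAGAAAGGGAAGGAAGGAAGAGGAAGAGAGGA
>sp1_h7
GAAGAAGGGAGGAAAGAAAGAAAGGAAAGAAAAGAAAAAAGGGAAAAAGGGAGGAGGGAGAAAGAGGAAAAGGAAAAGAA
GGAGAAGGGGGGAGAAAAGAAAAGAGAAAAAAAAAAGGAAGAAAGAAAAGAAAGGAAGAAGAAAAGAGGA
>sp1_h8
GAAGAAGAGAGAAAAAAAAGAAAGGAAAGAAAAAAAAAAAGAGAAAAAGGGAAAAGAAAAAAAGAGAAAAAGGAAAAGAA
GGAAAAAGGGGGAGAAAAGAAAAGAGAAAAAAAAAAGGAAAAAAAAAAAAAAAGGAAGAAGAAAAAAAAA
>sp1_h9
GAAAAAGAGAGAAAAAAAAAAAAGGAAAGAAAAAAAAAAAGAAAAAAAGAAAAAAAAAAAAAAGAAAAAAAGAAAAAAAA
GAAAAAAAAGGAAAAAAAAAAAAGAGAAAAAAAAAAGGAAAAAAAAAAAAAAAGAAAAAAAAAAAAAAAA
>sp1_h10
GAAAAAAAAAGAAAAAAAAAAAAGGAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
AAAAAAAAAGAAAAAAAAAAAAAGAAAAAAAAAAAAAGAAAAAAAAAAAAAAAGAAAAAAAAAAAAAAAA
>sp1_h11
AAAAAAAAAAGAAAAAAAAAAAAGAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
AAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAAAAAAAGAAAAAAAAAAAAAAAGAAAAAAAAAAAAAAAA
>sp1_h12
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGAAAAAAAAAAAAAAAA
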