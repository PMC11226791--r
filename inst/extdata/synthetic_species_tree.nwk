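(sp1:6,(sp2:5,(sp3:4,(sp4:3,(sp5:2,(sp6:1,sp7:1):1):1):1):1):1);
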