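# Printed counts: rows = siPAX8 induces / represses; cols = PPFP induces / represses / no change
32	62	81
47	24	50
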