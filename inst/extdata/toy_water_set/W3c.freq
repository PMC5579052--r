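               168
               184
               201
               214
               332
               346
               421
               446
               519
               562
               621
               679
              1609
              1615
              1622
              3519
              3544
              3561
              3714
              3722
              3731
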