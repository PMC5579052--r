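                44
                58
                73
                92
               108
               126
               151
               178
               204
               228
               252
               279
               334
               362
               398
               437
               476
               512
               558
               604
               662
               721
               784
               842
              1611
              1618
              1627
              1638
              1652
              3302
              3348
              3397
              3441
              3488
              3694
              3701
              3709
              3716
              3724
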