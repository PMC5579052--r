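                51
                66
                84
               101
               119
               142
               167
               193
               221
               247
               274
               309
               351
               389
               428
               472
               521
               574
               633
               701
               778
               861
               952
              1049
              1604
              1621
              1645
              1672
              1703
              2855
              2988
              3124
              3266
              3371
              3582
              3617
              3655
              3686
              3712
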