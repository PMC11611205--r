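country,fmi_p,mean_fmi_c
United States of America,0.932,0.742
Iceland,0.929,0.861
Norway,0.865,0.805
Denmark,0.842,0.804
Russia,0.838,0.774
Canada,0.834,0.726
United Kingdom,0.785,0.709
Chile,0.706,0.638
Argentina,0.694,0.666
South Korea,0.692,0.676
Spain,0.690,0.647
Japan,0.679,0.655
France,0.663,0.637
Morocco,0.622,0.616
Peru,0.613,0.591
Taiwan,0.609,0.588
Mexico,0.588,0.569
Indonesia,0.458,0.502
Turkey,0.431,0.534
India,0.422,0.442
Malaysia,0.386,0.423
Philippines,0.381,0.435
China,0.370,0.452
Thailand,0.313,0.416
Brazil,0.251,0.391
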