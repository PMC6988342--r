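beta	rho
0	0.00066
0.05	0.13918
0.1	0.27408
0.15	0.38864
0.2	0.4912
0.25	0.57857
0.3	0.64698
0.35	0.70178
0.4	0.74739
0.45	0.78449
0.5	0.81486
0.55	0.83971
0.6	0.85947
0.65	0.87622
0.7	0.89012
0.75	0.90247
0.8	0.91252
0.85	0.92165
0.9	0.92882
0.95	0.93544
1	0.94126
1.05	0.94594
1.1	0.95023
1.15	0.95404
1.2	0.95755
1.25	0.96028
1.3	0.96328
1.35	0.96573
1.4	0.9679
1.45	0.96998
1.5	0.9718
1.55	0.97331
1.6	0.97487
1.65	0.9762
1.7	0.97756
1.75	0.97835
1.8	0.97961
1.85	0.98066
1.9	0.98154
1.95	0.98236
2	0.98295
2.05	0.9838
2.1	0.98445
2.15	0.98502
2.2	0.98561
2.25	0.98614
2.3	0.98666
2.35	0.98708
2.4	0.98755
2.45	0.98792
2.5	0.98829
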