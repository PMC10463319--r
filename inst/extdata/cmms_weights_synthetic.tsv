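condition	weight
hearing_loss	1.715
depression_anxiety	0.803
painful_condition	2.418
hypertension	1.506
asthma	0.595
diabetes	2.209
alcohol_problems	1.298
condition_01	0.386
condition_02	2.001
condition_03	1.09
condition_04	0.178
condition_05	1.793
condition_06	0.881
condition_07	2.496
condition_08	1.584
condition_09	0.673
condition_10	2.288
condition_11	1.376
condition_12	0.465
condition_13	2.079
condition_14	1.168
condition_15	0.256
condition_16	1.871
condition_17	0.959
condition_18	2.574
condition_19	1.663
condition_20	0.751
condition_21	2.366
condition_22	1.454
condition_23	0.543
condition_24	2.157
condition_25	1.246
condition_26	0.334
condition_27	1.949
condition_28	1.038
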