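# Molar extinction coefficients of oxy- (eps_hbo) and deoxy-hemoglobin (eps_hb),
# natural-log convention, units mm^-1 uM^-1 (ln(10) folded in).
# Compiled by spline interpolation of classic tabulated anchor values onto a 2 nm grid.
# mu_a [mm^-1] = (eps_hbo*SaO2 + eps_hb*(1-SaO2)) * HbT[uM]
wavelength_nm,eps_hbo,eps_hb
700,6.6775e-05,0.000413153
702,6.68866e-05,0.000393386
704,6.72685e-05,0.000375041
706,6.79061e-05,0.000358098
708,6.87845e-05,0.000342541
710,6.9889e-05,0.000328351
712,7.12049e-05,0.00031551
714,7.27175e-05,0.000304
716,7.4412e-05,0.000293803
718,7.62737e-05,0.000284901
720,7.82879e-05,0.000277277
722,8.04371e-05,0.000270881
724,8.26935e-05,0.00026554
726,8.50266e-05,0.000261047
728,8.74059e-05,0.0002572
730,8.98008e-05,0.000253791
732,9.21949e-05,0.000250783
734,9.46277e-05,0.000248802
736,9.7153e-05,0.00024864
738,9.98243e-05,0.000251091
740,0.000102695,0.000256945
742,0.000105798,0.000266666
744,0.000109081,0.000279385
746,0.000112471,0.000293906
748,0.000115893,0.00030903
750,0.000119274,0.000323559
752,0.000122556,0.000336385
754,0.000125744,0.000346758
756,0.000128856,0.000354018
758,0.000131912,0.000357504
760,0.000134931,0.000356555
762,0.00013793,0.000350832
764,0.000140907,0.000341268
766,0.000143858,0.000329118
768,0.00014678,0.000315636
770,0.000149668,0.000302076
772,0.000152518,0.000289458
774,0.000155327,0.000277859
776,0.000158093,0.000267124
778,0.000160813,0.000257097
780,0.000163484,0.00024762
782,0.000166104,0.00023856
784,0.000168676,0.000229874
786,0.000171205,0.000221541
788,0.000173694,0.00021354
790,0.000176148,0.000205851
792,0.000178569,0.000198486
794,0.000180956,0.000191585
796,0.000183307,0.000185323
798,0.00018562,0.000179874
800,0.000187891,0.000175411
802,0.000190122,0.000172038
804,0.000192326,0.000169573
806,0.00019452,0.000167766
808,0.00019672,0.000166365
810,0.000198943,0.000165118
812,0.000201206,0.000163832
814,0.000203521,0.000162546
816,0.000205902,0.000161357
818,0.000208363,0.000160363
820,0.000210917,0.000159661
822,0.000213566,0.000159315
824,0.000216274,0.000159255
826,0.000218993,0.000159377
828,0.000221675,0.000159577
830,0.000224272,0.000159753
832,0.000226745,0.000159824
834,0.000229086,0.000159796
836,0.000231296,0.000159701
838,0.000233375,0.000159569
840,0.000235324,0.000159431
842,0.000237148,0.000159312
844,0.000238865,0.000159223
846,0.0002405,0.000159167
848,0.000242075,0.00015915
850,0.000243614,0.000159178
852,0.000245138,0.000159255
854,0.000246666,0.000159393
856,0.000248215,0.000159603
858,0.000249801,0.000159896
860,0.000251442,0.000160283
862,0.000253144,0.000160771
864,0.000254871,0.000161346
866,0.000256575,0.000161991
868,0.000258211,0.000162686
870,0.000259732,0.000163414
872,0.000261104,0.00016416
874,0.000262352,0.000164918
876,0.000263512,0.000165688
878,0.000264622,0.000166469
880,0.000265718,0.00016726
882,0.000266831,0.000168059
884,0.000267954,0.000168865
886,0.000269073,0.000169677
888,0.000270174,0.000170493
890,0.000271245,0.000171312
892,0.000272271,0.000172134
894,0.000273248,0.000172955
896,0.000274173,0.000173776
898,0.000275042,0.000174595
900,0.00027585,0.000175411
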