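# Synthetic chromophore specific-absorption basis (mm^-1 per percent concentration).
# Smooth Gaussian-mixture approximations to the literature tissue spectra;
# identical to osdensity::reference_basis(step = 5).
"wavelength_nm","eps_water","eps_lipid","eps_collagen","eps_oxyhb","eps_deoxyhb"
650,2.00002e-06,1.5e-06,4.2e-05,0.0016864595,0.019863376
655,2.0000476e-06,1.5e-06,4.1938367e-05,0.0017092211,0.018444599
660,2.0001257e-06,1.5e-06,4.1754606e-05,0.0017343905,0.017139272
665,2.0003827e-06,1.5e-06,4.1452092e-05,0.0017621897,0.015938345
670,2.0012965e-06,1.5e-06,4.1036341e-05,0.0017928537,0.014833536
675,2.004535e-06,1.5000001e-06,4.0514836e-05,0.0018266292,0.01381733
680,2.0153728e-06,1.5000007e-06,3.9896807e-05,0.0018637735,0.012883064
685,2.0486778e-06,1.5000047e-06,3.919296e-05,0.0019045518,0.01202515
690,2.1413932e-06,1.5000287e-06,3.8415169e-05,0.0019492345,0.011239513
695,2.3735328e-06,1.5001552e-06,3.7576148e-05,0.0019980935,0.010524317
700,2.8938682e-06,1.5007405e-06,3.6689113e-05,0.0020513974,0.0098809342
705,3.9338029e-06,1.5031174e-06,3.576744e-05,0.0021094061,0.0093149333
710,5.7785692e-06,1.5115827e-06,3.4824355e-05,0.0021723645,0.0088365299
715,8.6653346e-06,1.5379783e-06,3.3872636e-05,0.0022404944,0.0084596722
720,1.2612728e-05,1.6098938e-06,3.2924371e-05,0.0023139867,0.0081988856
725,1.7253573e-05,1.7806237e-06,3.1990752e-05,0.0023929924,0.0080635348
730,2.1796799e-05,2.1323953e-06,3.1081946e-05,0.0024776127,0.0080503286
735,2.5217234e-05,2.7576683e-06,3.0207011e-05,0.0025678897,0.0081364077
740,2.6641047e-05,3.7072766e-06,2.9373902e-05,0.0026637973,0.0082763953
745,2.5738617e-05,4.9186969e-06,2.8589549e-05,0.0027652322,0.0084064179
750,2.2890789e-05,6.1728047e-06,2.7860009e-05,0.002872007,0.0084558711
755,1.9022279e-05,7.1364784e-06,2.7190706e-05,0.0029838451,0.008364278
760,1.5208105e-05,7.5e-06,2.6586758e-05,0.0031003776,0.0080976294
765,1.2286742e-05,7.1364784e-06,2.6053365e-05,0.0032211445,0.0076579372
770,1.0668041e-05,6.1728047e-06,2.5596278e-05,0.0033455973,0.0070820959
775,1.0368105e-05,4.9186969e-06,2.5222318e-05,0.0034731075,0.0064305189
780,1.1172561e-05,3.7072766e-06,2.4939913e-05,0.0036029765,0.0057701458
785,1.2802646e-05,2.7576683e-06,2.475963e-05,0.0037344506,0.005158201
790,1.5012854e-05,2.1323953e-06,2.4694653e-05,0.003866737,0.0046318542
795,1.7616363e-05,1.7806237e-06,2.4761136e-05,0.0039990234,0.004205726
800,2.0469358e-05,1.6098938e-06,2.4978365e-05,0.0041304975,0.0038758824
805,2.3445806e-05,1.5379783e-06,2.5368659e-05,0.0042603665,0.0036270866
810,2.6419634e-05,1.5115827e-06,2.5956922e-05,0.0043878767,0.0034400527
815,2.9258243e-05,1.5031174e-06,2.6769781e-05,0.0045123295,0.0032966559
820,3.1825076e-05,1.5007405e-06,2.7834261e-05,0.0046330964,0.0031825524
825,3.3987599e-05,1.5001552e-06,2.9175995e-05,0.0047496289,0.0030877121
830,3.5627632e-05,1.500029e-06,3.0816979e-05,0.004861467,0.003005762
835,3.6651745e-05,1.5000066e-06,3.2772986e-05,0.0049682418,0.0029329305
840,3.7000004e-05,1.5000131e-06,3.505078e-05,0.0050696767,0.0028670716
845,3.6651758e-05,1.5000725e-06,3.7645332e-05,0.0051655843,0.0028069565
850,3.5627679e-05,1.5003823e-06,4.0537319e-05,0.0052558613,0.0027518327
855,3.3987758e-05,1.5018187e-06,4.3691183e-05,0.0053404816,0.0027011829
860,3.1825571e-05,1.5078045e-06,4.705404e-05,0.0054194873,0.0026546052
865,2.9259687e-05,1.5302039e-06,5.0555715e-05,0.0054929796,0.0026117586
870,2.6423548e-05,1.6054201e-06,5.411008e-05,0.0055611095,0.0025723398
875,2.3455576e-05,1.8318356e-06,5.7617791e-05,0.0056240679,0.0025360734
880,2.0491645e-05,2.4420211e-06,6.0970391e-05,0.0056820766,0.0025027068
885,1.7662522e-05,3.9117741e-06,6.4055608e-05,0.0057353805,0.0024720081
890,1.509955e-05,7.068671e-06,6.6763549e-05,0.0057842395,0.002443764
895,1.2952537e-05,1.3095967e-05,6.899339e-05,0.0058289222,0.0024177781
900,1.1424085e-05,2.3277392e-05,7.0660116e-05,0.0058697005,0.0023938699
905,1.0823393e-05,3.8385341e-05,7.1700868e-05,0.0059068448,0.0023718733
910,1.1638212e-05,5.7845778e-05,7.2080503e-05,0.0059406203,0.0023516355
915,1.4614685e-05,7.9133533e-05,7.1796133e-05,0.0059712843,0.0023330158
920,2.0821114e-05,9.7985014e-05,7.0880509e-05,0.0059990835,0.0023158849
925,3.1656099e-05,0.00010968879,6.9404338e-05,0.0060242529,0.0023001236
930,4.8751453e-05,0.00011100011,6.7477658e-05,0.0060470145,0.0022856226
935,7.3726231e-05,0.00010164172,6.5250456e-05,0.0060675768,0.002272281
940,0.00010778014,8.4464315e-05,6.291258e-05,0.0060861345,0.0022600061
945,0.00015117397,6.4164024e-05,6.0692722e-05,0.0061028685,0.0022487127
950,0.00020271798,4.535961e-05,5.885587e-05,0.0061179462,0.0022383223
955,0.00025944683,3.1109135e-05,5.7698162e-05,0.006131522,0.0022287626
960,0.00031666458,2.2467819e-05,5.7537739e-05,0.0061437378,0.0022199673
965,0.00036847089,1.8951638e-05,5.8700035e-05,0.0061547235,0.0022118752
970,0.00040873554,1.9348816e-05,6.1496266e-05,0.006164598,0.0022044301
975,0.00043231892,2.2381023e-05,6.6194717e-05,0.0061734695,0.0021975803
980,0.00043621195,2.7026039e-05,7.2985817e-05,0.0061814366,0.0021912782
985,0.00042025259,3.257237e-05,8.1943867e-05,0.0061885889,0.00218548
990,0.0003871905,3.855799e-05,9.2990183e-05,0.0061950075,0.0021801453
995,0.00034207644,4.4698685e-05,0.00010586403,0.006200766,0.0021752372
1000,0.00029116807,5.0835199e-05,0.00012010835,0.0062059309,0.0021707216
1005,0.00024068133,5.6883072e-05,0.00013507652,0.0062079366,0.0021665669
1010,0.00019572766,6.2764815e-05,0.00014996425,0.0062042113,0.0021627445
1015,0.00015967139,6.8325543e-05,0.00016386685,0.0061948183,0.0021592277
1020,0.00013397619,7.3259126e-05,0.00017585752,0.0061798364,0.0021559921
1025,0.00011845628,7.7084939e-05,0.00018507809,0.0061593587,0.0021530152
1030,0.00011176006,7.9205281e-05,0.00019082992,0.0061334932,0.0021502763
1035,0.00011190408,7.9042359e-05,0.00019265165,0.0061023622,0.0021477564
1040,0.00011672466,7.6215178e-05,0.00019037143,0.0060661018,0.0021454379
1045,0.00012418565,7.0691002e-05,0.00018412534,0.0060248612,0.0021433049
1050,0.00013254335,6.2848875e-05,0.0001743387,0.0059788027,0.0021413424
1055,0.00014040456,5.3424951e-05,0.00016167372,0.0059281005,0.0021395368
1060,0.00014672336,4.335629e-05,0.00014695195,0.0058729402,0.0021378756
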