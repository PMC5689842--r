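"depth_cm","pdd_percent"
0,30
0.05,34.5888888888889
0.1,39.0222222222222
0.15,43.3
0.2,47.4222222222222
0.25,51.3888888888889
0.3,55.2
0.35,58.8555555555555
0.4,62.3555555555556
0.45,65.7
0.5,68.8888888888889
0.55,71.9222222222222
0.6,74.8
0.65,77.5222222222222
0.7,80.0888888888889
0.75,82.5
0.8,84.7555555555555
0.85,86.8555555555556
0.9,88.8
0.95,90.5888888888889
1,92.2222222222222
1.05,93.7
1.1,95.0222222222222
1.15,96.1888888888889
1.2,97.2
1.25,98.0555555555555
1.3,98.7555555555555
1.35,99.3
1.4,99.6888888888889
1.45,99.9222222222222
1.5,100
1.75,98.8565872247913
2,97.7262483773277
2.25,96.6088339686492
2.5,95.5041962190715
2.75,94.4121890386422
3,93.3326680078202
3.25,92.2654903583757
3.5,91.210514954509
3.75,90.1676022741855
4,89.1366143906831
4.25,88.1174149543515
4.5,87.1098691745798
4.75,86.1138438019701
5,85.1292071107151
5.25,84.1558288811773
5.5,83.1935803826672
5.75,82.2423343564182
6,81.3019649987571
6.25,80.3723479444656
6.5,79.4533602503334
6.75,78.5448803788985
7,77.6467881823738
7.25,76.7589648867573
7.5,75.8812930761241
7.75,75.0136566770982
8,74.1559409435011
8.25,73.3080324411768
8.5,72.4698190329903
8.75,71.6411898639964
9,70.82203534678
9.25,70.0122471469621
9.5,69.211718168873
9.75,68.4203425413887
10,67.6380156039289
10.25,66.8646338926159
10.5,66.1000951265913
10.75,65.3442981944887
11,64.5971431410624
11.25,63.8585311539677
11.5,63.1283645506926
11.75,62.4065467656397
12,61.6929823373547
12.25,60.9875768959022
12.5,60.2902371503842
12.75,59.6008708766031
13,58.9193869048644
13.25,58.2456951079195
13.5,57.5797063890464
13.75,56.9213326702664
14,56.2704868806956
14.25,55.6270829450296
14.5,54.9910357721602
14.75,54.3622612439217
15,53.7406762039664
15.25,53.1261984467667
15.5,52.5187467067436
15.75,51.9182406475192
16,51.3246008512919
16.25,50.7377488083333
16.5,50.1576069066056
16.75,49.5840984214965
17,49.017147505673
17.25,48.4566791790503
17.5,47.9026193188751
17.75,47.3548946499235
18,46.8134327348097
18.25,46.2781619644061
18.5,45.7490115483733
18.75,45.2259115057975
19,44.7087926559356
19.25,44.1975866090661
19.5,43.6922257574441
19.75,43.1926432663605
20,42.6987730653026
20.25,42.2105498392166
20.5,41.7279090198691
20.75,41.2507867773085
21,40.7791200114226
21.25,40.3128463435943
21.5,39.8519041084514
21.75,39.3962323457115
22,38.9457707921197
22.25,38.5004598734791
22.5,38.0602406967716
22.75,37.6250550423696
23,37.1948453563358
23.25,36.7695547428124
23.5,36.3491269564957
23.75,35.9335063951983
24,35.5226380924951
24.25,35.1164677104544
24.5,34.714941532451
24.75,34.3180064560628
25,33.9256099860472
25.25,33.5377002273992
25.5,33.154225878488
25.75,32.7751362242718
26,32.4003811295914
26.25,32.0299110325394
26.5,31.6636769379053
26.75,31.3016304106965
27,30.943723569732
27.25,30.5899090813104
27.5,30.24014015295
27.75,29.8943705272001
28,29.5525544755239
28.25,29.2146467922503
28.5,28.8806027885956
28.75,28.5503782867535
29,28.2239296140523
29.25,27.9012135971793
29.5,27.5821875564709
29.75,27.2668093002682
30,26.9550371193372
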