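# Table of FreeSurfer cortical parcellation anatomical statistics (synthetic fixture, lh)
# anatomy_type surface
# Measure Cortex, CortexVol, Total cortical gray matter volume, 240000.0, mm^3
# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd MeanCurv GausCurv FoldInd CurvInd
bankssts                     1155     924     2309  1.913 0.450 0.120 0.025 12 1.2
caudalanteriorcingulate      1254    1003     2508  2.628 0.450 0.120 0.025 12 1.2
caudalmiddlefrontal          3115    2492     6230  2.290 0.450 0.120 0.025 12 1.2
cuneus                       2234    1787     4468  2.940 0.450 0.120 0.025 12 1.2
entorhinal                   1116     893     2232  2.081 0.450 0.120 0.025 12 1.2
frontalpole                   600     480     1200  2.253 0.450 0.120 0.025 12 1.2
fusiform                     4110    3288     8220  2.564 0.450 0.120 0.025 12 1.2
inferiorparietal             6175    4940    12351  2.421 0.450 0.120 0.025 12 1.2
inferiortemporal             4929    3943     9857  2.953 0.450 0.120 0.025 12 1.2
insula                       3654    2923     7308  3.168 0.450 0.120 0.025 12 1.2
isthmuscingulate             1261    1009     2522  2.475 0.450 0.120 0.025 12 1.2
lateraloccipital             5608    4486    11214  3.102 0.450 0.120 0.025 12 1.2
lateralorbitofrontal         3588    2870     7176  3.084 0.450 0.120 0.025 12 1.2
lingual                      3532    2826     7064  2.397 0.450 0.120 0.025 12 1.2
medialorbitofrontal          2430    1944     4859  1.954 0.450 0.120 0.025 12 1.2
middletemporal               5559    4447    11117  2.947 0.450 0.120 0.025 12 1.2
paracentral                  1864    1491     3727  3.171 0.450 0.120 0.025 12 1.2
parahippocampal              1165     932     2330  2.997 0.450 0.120 0.025 12 1.2
parsopercularis              2261    1809     4522  2.569 0.450 0.120 0.025 12 1.2
parsorbitalis                1270    1016     2541  2.344 0.450 0.120 0.025 12 1.2
parstriangularis             1905    1524     3809  2.202 0.450 0.120 0.025 12 1.2
pericalcarine                1844    1475     3688  2.828 0.450 0.120 0.025 12 1.2
postcentral                  4761    3809     9522  2.988 0.450 0.120 0.025 12 1.2
posteriorcingulate           1812    1450     3626  3.090 0.450 0.120 0.025 12 1.2
precentral                   6148    4918    12296  2.978 0.450 0.120 0.025 12 1.2
precuneus                    4521    3617     9043  2.688 0.450 0.120 0.025 12 1.2
rostralanteriorcingulate     1188     950     2374  2.375 0.450 0.120 0.025 12 1.2
rostralmiddlefrontal         7228    5782    14455  1.927 0.450 0.120 0.025 12 1.2
superiorfrontal              9649    7719    19297  1.965 0.450 0.120 0.025 12 1.2
superiorparietal             5495    4396    10991  2.815 0.450 0.120 0.025 12 1.2
superiortemporal             5440    4352    10880  2.706 0.450 0.120 0.025 12 1.2
supramarginal                4495    3596     8991  2.605 0.450 0.120 0.025 12 1.2
temporalpole                 1181     945     2363  1.998 0.450 0.120 0.025 12 1.2
transversetemporal            562     450     1126  2.243 0.450 0.120 0.025 12 1.2
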