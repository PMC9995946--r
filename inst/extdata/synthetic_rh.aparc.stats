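# Table of FreeSurfer cortical parcellation anatomical statistics (synthetic fixture, rh)
# anatomy_type surface
# Measure Cortex, CortexVol, Total cortical gray matter volume, 240000.0, mm^3
# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd MeanCurv GausCurv FoldInd CurvInd
bankssts                     1130     904     2260  2.955 0.450 0.120 0.025 12 1.2
caudalanteriorcingulate      1130     904     2261  2.980 0.450 0.120 0.025 12 1.2
caudalmiddlefrontal          2865    2292     5730  2.487 0.450 0.120 0.025 12 1.2
cuneus                       2298    1838     4594  2.099 0.450 0.120 0.025 12 1.2
entorhinal                   1276    1021     2552  2.480 0.450 0.120 0.025 12 1.2
frontalpole                   595     476     1190  1.824 0.450 0.120 0.025 12 1.2
fusiform                     3940    3152     7880  2.933 0.450 0.120 0.025 12 1.2
inferiorparietal             6816    5453    13632  1.926 0.450 0.120 0.025 12 1.2
inferiortemporal             4888    3910     9774  2.763 0.450 0.120 0.025 12 1.2
insula                       3522    2818     7044  2.626 0.450 0.120 0.025 12 1.2
isthmuscingulate             1140     912     2279  2.021 0.450 0.120 0.025 12 1.2
lateraloccipital             5378    4302    10754  3.073 0.450 0.120 0.025 12 1.2
lateralorbitofrontal         3499    2799     6998  3.196 0.450 0.120 0.025 12 1.2
lingual                      3676    2941     7353  2.272 0.450 0.120 0.025 12 1.2
medialorbitofrontal          2315    1852     4631  2.064 0.450 0.120 0.025 12 1.2
middletemporal               5194    4155    10387  2.292 0.450 0.120 0.025 12 1.2
paracentral                  1784    1427     3567  3.185 0.450 0.120 0.025 12 1.2
parahippocampal              1192     954     2385  2.740 0.450 0.120 0.025 12 1.2
parsopercularis              2342    1874     4685  2.626 0.450 0.120 0.025 12 1.2
parsorbitalis                1218     974     2434  3.133 0.450 0.120 0.025 12 1.2
parstriangularis             1708    1366     3416  2.118 0.450 0.120 0.025 12 1.2
pericalcarine                1698    1358     3394  2.236 0.450 0.120 0.025 12 1.2
postcentral                  4855    3884     9709  3.194 0.450 0.120 0.025 12 1.2
posteriorcingulate           1804    1443     3607  2.859 0.450 0.120 0.025 12 1.2
precentral                   6444    5155    12887  2.618 0.450 0.120 0.025 12 1.2
precuneus                    4905    3924     9809  2.599 0.450 0.120 0.025 12 1.2
rostralanteriorcingulate     1238     990     2474  3.084 0.450 0.120 0.025 12 1.2
rostralmiddlefrontal         7386    5909    14773  1.892 0.450 0.120 0.025 12 1.2
superiorfrontal              9211    7369    18422  2.618 0.450 0.120 0.025 12 1.2
superiorparietal             5490    4392    10980  2.408 0.450 0.120 0.025 12 1.2
superiortemporal             5176    4141    10353  3.139 0.450 0.120 0.025 12 1.2
supramarginal                4838    3870     9676  2.148 0.450 0.120 0.025 12 1.2
temporalpole                 1245     996     2491  2.991 0.450 0.120 0.025 12 1.2
transversetemporal            635     508     1270  2.889 0.450 0.120 0.025 12 1.2
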