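# Title Segmentation Statistics (synthetic fixture)
# generating_program mri_segstats
# anatomy_type volume
# Measure BrainSeg, BrainSegVol, Brain Segmentation Volume, 1150000.000000, mm^3
# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, 1500000.000000, mm^3
# ColHeaders  Index SegId NVoxels Volume_mm3 StructName normMean
  1   1    9076     9076.2  Left-Lateral-Ventricle  85.0
  2   2    8652     8652.4  Right-Lateral-Ventricle  85.0
  3   3     356      356.4  Left-Inf-Lat-Vent  85.0
  4   4     367      367.2  Right-Inf-Lat-Vent  85.0
  5   5  230805   230804.9  Left-Cerebral-White-Matter  85.0
  6   6  240732   240732.1  Right-Cerebral-White-Matter  85.0
  7   7  244114   244114.3  Left-Cerebral-Cortex  85.0
  8   8  235070   235069.9  Right-Cerebral-Cortex  85.0
  9   9    6704     6703.7  Left-Thalamus  85.0
 10  10    6579     6579.2  Right-Thalamus  85.0
 11  11    3517     3517.1  Left-Caudate  85.0
 12  12    3502     3501.9  Right-Caudate  85.0
 13  13    4944     4943.9  Left-Putamen  85.0
 14  14    5170     5169.8  Right-Putamen  85.0
 15  15    1732     1731.9  Left-Pallidum  85.0
 16  16    1724     1723.8  Right-Pallidum  85.0
 17  17    4000     4000.0  Left-Hippocampus  85.0
 18  18    4200     4200.0  Right-Hippocampus  85.0
 19  19    1479     1478.7  Left-Amygdala  85.0
 20  20    1440     1440.4  Right-Amygdala  85.0
 21  21     499      499.1  Left-Accumbens-area  85.0
 22  22     504      503.5  Right-Accumbens-area  85.0
 23  23   21000    21000.0  Brain-Stem  80.0
 24  24    1100     1100.0  CSF  30.0
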