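##TITLE=synthetic dried-serum example spectrum (generated, not measured)
##JCAMP-DX=4.24
##DATA TYPE=INFRARED SPECTRUM
##XUNITS=1/CM
##YUNITS=ABSORBANCE
##XFACTOR=1
##YFACTOR=0.0001
##FIRSTX=1600
##LASTX=1698
##NPOINTS=50
##DELTAX=2
##XYDATA=(X++(Y..Y))
1600 1353 1465 1581 1700 1821 1944 2066 2188 2307
1618 2422 2532 2635 2729 2814 2887 2948 2995 3028
1636 3045 3046 3030 2998 2950 2887 2810 2720 2619
1654 2508 2390 2266 2139 2010 1882 1756 1634 1517
1672 1406 1303 1208 1121 1044 975 915 864 821
1690 786 759 738 724 715
##END=
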