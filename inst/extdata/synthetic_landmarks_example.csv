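subject_id,age,true_stage,point_label,x_mm,y_mm
S0001,8.30271835558918,1,C2a,33.556128,31.492817
S0001,8.30271835558918,1,C2p,22.297555,34.610272
S0001,8.30271835558918,1,C2d,27.926841,33.051545
S0001,8.30271835558918,1,C3la,32.613860,22.651613
S0001,8.30271835558918,1,C3lp,20.324033,25.219529
S0001,8.30271835558918,1,C3ua,30.655342,28.017719
S0001,8.30271835558918,1,C3up,21.406172,30.398557
S0001,8.30271835558918,1,C3um,26.030757,29.208138
S0001,8.30271835558918,1,C3d,26.468946,23.935571
S0001,8.30271835558918,1,C4la,30.158982,9.486027
S0001,8.30271835558918,1,C4lp,17.395943,12.521984
S0001,8.30271835558918,1,C4ua,27.983816,15.036087
S0001,8.30271835558918,1,C4up,19.579305,21.700746
S0001,8.30271835558918,1,C4um,23.781560,18.368417
S0001,8.30271835558918,1,C4d,23.777463,11.004005
S0002,9.44445761009053,2,C2a,41.277083,38.283519
S0002,9.44445761009053,2,C2p,29.034880,40.008718
S0002,9.44445761009053,2,C2d,35.179254,39.311257
S0002,9.44445761009053,2,C3la,40.087353,24.863714
S0002,9.44445761009053,2,C3lp,27.214135,26.632545
S0002,9.44445761009053,2,C3ua,39.587053,31.630098
S0002,9.44445761009053,2,C3up,28.455140,35.664342
S0002,9.44445761009053,2,C3um,34.021096,33.647220
S0002,9.44445761009053,2,C3d,33.749010,26.463288
S0002,9.44445761009053,2,C4la,36.623310,11.935617
S0002,9.44445761009053,2,C4lp,25.579274,13.230907
S0002,9.44445761009053,2,C4ua,40.773084,18.664892
S0002,9.44445761009053,2,C4up,26.693452,22.730727
S0002,9.44445761009053,2,C4um,33.733268,20.697810
S0002,9.44445761009053,2,C4d,31.120339,12.745662
S0003,11.0860350628705,3,C2a,-23.494534,81.041628
S0003,11.0860350628705,3,C2p,-34.118333,82.413681
S0003,11.0860350628705,3,C2d,-28.685845,82.661367
S0003,11.0860350628705,3,C3la,-24.809394,65.494798
S0003,11.0860350628705,3,C3lp,-36.667911,67.621799
S0003,11.0860350628705,3,C3ua,-22.985924,77.236688
S0003,11.0860350628705,3,C3up,-34.848805,77.763737
S0003,11.0860350628705,3,C3um,-28.917364,77.500213
S0003,11.0860350628705,3,C3d,-30.473345,68.037448
S0003,11.0860350628705,3,C4la,-25.939618,48.184908
S0003,11.0860350628705,3,C4lp,-38.931160,49.696748
S0003,11.0860350628705,3,C4ua,-28.360584,56.782701
S0003,11.0860350628705,3,C4up,-37.351851,63.268062
S0003,11.0860350628705,3,C4um,-32.856217,60.025382
S0003,11.0860350628705,3,C4d,-32.396728,49.273049
S0004,15.4743844290368,4,C2a,6.154443,58.140282
S0004,15.4743844290368,4,C2p,-6.962404,59.524584
S0004,15.4743844290368,4,C2d,-0.190901,60.851456
S0004,15.4743844290368,4,C3la,1.679991,39.388451
S0004,15.4743844290368,4,C3lp,-9.966605,41.269446
S0004,15.4743844290368,4,C3ua,3.456055,51.272560
S0004,15.4743844290368,4,C3up,-7.888467,54.136692
S0004,15.4743844290368,4,C3um,-2.216206,52.704626
S0004,15.4743844290368,4,C3d,-3.860226,42.081705
S0004,15.4743844290368,4,C4la,4.328095,24.596381
S0004,15.4743844290368,4,C4lp,-12.065011,26.840875
S0004,15.4743844290368,4,C4ua,2.864776,36.452784
S0004,15.4743844290368,4,C4up,-10.570760,37.754433
S0004,15.4743844290368,4,C4um,-3.852992,37.103609
S0004,15.4743844290368,4,C4d,-3.581520,27.814342
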