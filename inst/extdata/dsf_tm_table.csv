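variant,osmolyte,conc_M,tm_c,tm_err,dtm_printed
WT,none,0,55.1,0.1,NA
WT,trehalose,0.025,54.6,0.1,-0.5
WT,trehalose,0.050,54.9,0.1,-0.2
WT,trehalose,0.125,55.3,0.1,0.2
WT,trehalose,0.250,56.5,0.1,1.4
WT,trehalose,0.500,57.8,0.1,2.7
WT,trehalose,0.750,60.2,0.1,5.1
WT,TMAO,0.05,50.1,0.1,0.5
WT,TMAO,0.2,51.3,0.1,1.0
WT,TMAO,0.5,52.0,0.1,3.0
WT,TMAO,0.75,54.0,0.1,4.8
WT,TMAO,1,48.8,0.1,5.8
D122Y,none,0,48.8,0.1,NA
D122Y,trehalose,0.025,50.1,0.1,3.9
D122Y,trehalose,0.050,50.7,0.1,4.5
D122Y,trehalose,0.125,50.3,0.1,4.1
D122Y,trehalose,0.250,50.3,0.1,4.1
D122Y,trehalose,0.500,53.4,0.1,7.2
D122Y,trehalose,0.750,54.1,0.1,7.9
D122Y,TMAO,0.05,48.8,0.1,2.6
D122Y,TMAO,0.2,50.1,0.1,4.0
D122Y,TMAO,0.5,51.3,0.1,5.1
D122Y,TMAO,0.75,52.0,0.1,5.8
D122Y,TMAO,1,54.0,0.1,7.8
I154F,none,0,39.1,0.1,NA
I154F,trehalose,0.025,39.6,0.1,0.5
I154F,trehalose,0.050,39.5,0.1,0.4
I154F,trehalose,0.125,38.3,0.1,-0.8
I154F,trehalose,0.250,39.6,0.1,0.5
I154F,trehalose,0.500,40.3,0.1,1.2
I154F,trehalose,0.750,39.3,0.2,0.2
I154F,TMAO,0.05,39.7,0.1,0.6
I154F,TMAO,0.2,38.4,0.1,1.3
I154F,TMAO,0.5,40.9,0.1,1.8
I154F,TMAO,0.75,42.2,0.1,3.1
I154F,TMAO,1,41.6,0.2,2.5
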