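pair_no,territory,male,male_natal,female,female_natal,fp_published,first_year,last_year
1,AG,GW187m,,GW016f,N,0,2009,2015
2,AH,GW194m,AG,GW239f,,0,2013,2014
3,AH,GW194m,AG,XII,,0,2015,2015
4,BA,GW243m,,GW195f,AG,0,2013,2015
5,BE,GW188m,AG,GW191f,AG,0.25,2013,2015
6,BI,GW411m,,GW541f,DZ,0,2015,2015
7,CLH,GW208m,AG,GW340f,,0,2013,2013
8,CO,GW599m,RT,GW323f,GKL,0.016,2015,2015
9,CUN,VIII,,GW178f,DN,0,2015,2015
10,CUX,GW339m,MU,GW203f,AG,0.055,2015,2015
11,DN,GW038m,NO,GW024f,N,0.094,2008,2011
12,DN,VI,,GW114f,DN,0,2012,2012
13,DN,GW038m,NO,GW114f,DN,0.328,2013,2013
14,DN,GW301m,,GW114f,DN,0,2014,2014
15,DN,VII,,GW114f,DN,0,2015,2015
16,DZ,GW042m,,II,,0,2006,2008
17,DZ,GW042m,,GW023f,,0,2009,2010
18,DZ,GW105m,,GW087f,NO,0,2012,2013
19,DZ,GW381m,,GW087f,NO,0,2014,2015
20,ES,GW218m,LE,GW242f,LE,0.25,2014,2014
21,ES,XI,,GW242f,LE,0,2015,2015
22,FHB,GW128m,WE,GW347f,WE,0.156,2014,2014
23,GA,GW215m,DN,GW262f,,0,2013,2014
24,GKL,GW237m,,GW196f,AG,0,2012,2015
25,GLH,GW250m,SPJ,GW342f,,0,2014,2014
26,GLH,GW349m,SPJ,GW342f,,0,2015,2015
27,GR,GW111m,KH,GW245f,,0,2013,2015
28,GRH,GW149m,SPJ,GW306f,GR,0.008,2015,2015
29,HF,GW233m,GKL,GW227f,AG,0.125,2014,2015
30,HO,GW283m,SP,GW277f,SP,0.379,2015,2015
31,HW,V,,GW085f,SL,0,2012,2013
32,JW,IV,,GW132f,N,0,2011,2011
33,KH,GW104m,,GW056f,SL,0,2011,2015
34,KHB,GW287m,MI,GW116f,DN,0.086,2015,2015
35,KN,GW586m,,GW180f,MI,0,2015,2015
36,KO,GW097m,NO,GW116f,DN,0.203,2013,2013
37,LB,III,,GW131f,MH,0,2011,2011
38,LB,GW144m,,GW098f,SP,0,2013,2013
39,LB,GW249m,,GW098f,SP,0,2014,2014
40,LB,GW249m,,GW348f,AG,0,2015,2015
41,LE,GW161m,,GW185f,AG,0,2011,2013
42,LE,GW186m,AG,GW185f,AG,0.25,2014,2015
43,LH,GW288m,DN,GW293f,KH,0.027,2014,2014
44,LH,GW288m,DN,IX,,0,2015,2015
45,LUE,GW153m,,GW258f,,0,2014,2015
46,MI,GW025m,NO,GW026f,N,0.094,2008,2010
47,MI,GW042m,,GW026f,N,0,2011,2011
48,MI,GW295m,,GW026f,N,0,2012,2012
49,MI,GW014m,DZ,GW026f,N,0,2013,2015
50,MI2,GW014m,DZ,GW050f,MI,0,2012,2012
51,MOE,GW333m,GKL,XIII,,0,2015,2015
52,MU,GW213m,SL,GW214f,NO,0.094,2012,2013
53,MU,GW213m,SL,GW263f,MU,0.297,2014,2015
54,N,GW001m,,GW006f,MH,0,2005,2008
55,NO,GW008m,MH,GW012f,MH,0.125,2005,2011
56,NO,GW106m,,GW071f,NO,0,2012,2013
57,NO,GW038m,NO,GW071f,NO,0.313,2014,2015
58,NY,GW096m,,GW031f,DZ,0,2011,2015
59,RM,GW260m,,GW202f,AG,0,2014,2014
60,RT,GW294m,,GW112f,MI,0,2014,2015
61,RU,GW404m,KH,X,,0,2014,2014
62,RU,GW404m,KH,GW177f,DN,0.027,2015,2015
63,SE,GW128m,WE,GW130f,N,0.125,2012,2012
64,SF,GW362m,,GW351f,SPJ,0,2015,2015
65,SL,GW014m,DZ,GW006f,MH,0,2009,2011
66,SL,GW068m,NO,GW067f,SL,0.094,2013,2014
67,SL,GW566m,SP,GW067f,SL,0.102,2015,2015
68,SP,GW037m,NO,GW058f,MI,0.203,2011,2015
69,SPJ,GW207m,,GW140f,WE,0,2012,2015
70,STO,GW589m,,GW552f,,0,2015,2015
71,TL,GW246m,,GW169f,SP,0,2013,2013
72,UEM,GW223m,N,GW257f,GKL,0.063,2014,2015
73,WE,GW123m,,GW007f,N,0,2009,2010
74,WE,GW070m,SL,GW139f,WE,0.063,2012,2012
75,WI,GW367m,BE,GW163f,LE,0.125,2015,2015
76,ZIH,GW417m,,GW497f,CLH,0,2015,2015
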