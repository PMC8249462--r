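id,sire,dam,sex,natal_pack,birth_year
I,0,0,M,,
GW064m,0,0,M,,
GW023f,0,0,F,,
GW001m,0,0,M,,
GW042m,0,0,M,,
II,0,0,F,,
GW187m,0,0,M,,
GW239f,0,0,F,,
XII,0,0,F,,
GW243m,0,0,M,,
GW411m,0,0,M,,
GW340f,0,0,F,,
VIII,0,0,M,,
GW105m,0,0,M,,
GW381m,0,0,M,,
XI,0,0,M,,
GW262f,0,0,F,,
GW237m,0,0,M,,
GW342f,0,0,F,,
GW245f,0,0,F,,
V,0,0,M,,
IV,0,0,M,,
GW104m,0,0,M,,
GW586m,0,0,M,,
III,0,0,M,,
GW144m,0,0,M,,
GW249m,0,0,M,,
GW161m,0,0,M,,
IX,0,0,F,,
GW153m,0,0,M,,
GW258f,0,0,F,,
GW295m,0,0,M,,
XIII,0,0,F,,
GW106m,0,0,M,,
GW096m,0,0,M,,
GW260m,0,0,M,,
GW294m,0,0,M,,
X,0,0,F,,
GW362m,0,0,M,,
GW589m,0,0,M,,
GW552f,0,0,F,,
GW246m,0,0,M,,
GW123m,0,0,M,,
GW417m,0,0,M,,
GW207m,0,0,M,,
GW301m,0,0,M,,
VI,0,0,M,,
VII,0,0,M,,
GW012f,I,GW023f,F,MH,2001
GW006f,GW064m,GW023f,F,MH,2002
GW008m,GW064m,GW023f,M,MH,2002
GW131f,GW064m,GW023f,F,MH,2004
GW016f,GW001m,GW006f,F,N,2006
GW024f,GW001m,GW006f,F,N,2006
GW026f,GW001m,GW006f,F,N,2006
GW007f,GW001m,GW006f,F,N,2007
GW130f,GW001m,GW006f,F,N,2008
GW132f,GW001m,GW006f,F,N,2008
GW223m,GW001m,GW006f,M,N,2008
GW025m,GW008m,GW012f,M,NO,2005
GW038m,GW008m,GW012f,M,NO,2005
GW037m,GW008m,GW012f,M,NO,2008
GW087f,GW008m,GW012f,F,NO,2009
GW068m,GW008m,GW012f,M,NO,2010
GW071f,GW008m,GW012f,F,NO,2010
GW097m,GW008m,GW012f,M,NO,2010
GW214f,GW008m,GW012f,F,NO,2010
GW014m,GW042m,II,M,DZ,2006
GW031f,GW042m,II,F,DZ,2008
GW541f,GW105m,GW087f,F,DZ,2013
GW185f,GW187m,GW016f,F,AG,2009
GW196f,GW187m,GW016f,F,AG,2010
GW194m,GW187m,GW016f,M,AG,2011
GW195f,GW187m,GW016f,F,AG,2011
GW188m,GW187m,GW016f,M,AG,2011
GW191f,GW187m,GW016f,F,AG,2011
GW208m,GW187m,GW016f,M,AG,2011
GW203f,GW187m,GW016f,F,AG,2012
GW227f,GW187m,GW016f,F,AG,2012
GW202f,GW187m,GW016f,F,AG,2012
GW186m,GW187m,GW016f,M,AG,2012
GW348f,GW187m,GW016f,F,AG,2013
GW056f,GW014m,GW006f,F,SL,2009
GW070m,GW014m,GW006f,M,SL,2009
GW213m,GW014m,GW006f,M,SL,2009
GW085f,GW014m,GW006f,F,SL,2010
GW067f,GW014m,GW006f,F,SL,2011
GW058f,GW025m,GW026f,F,MI,2008
GW050f,GW025m,GW026f,F,MI,2009
GW287m,GW042m,GW026f,M,MI,2011
GW112f,GW042m,GW026f,F,MI,2011
GW180f,GW014m,GW026f,F,MI,2013
GW114f,GW038m,GW024f,F,DN,2009
GW116f,GW038m,GW024f,F,DN,2010
GW178f,GW038m,GW024f,F,DN,2011
GW215m,GW038m,GW024f,M,DN,2011
GW177f,VI,GW114f,F,DN,2012
GW288m,VI,GW114f,M,DN,2012
GW128m,GW123m,GW007f,M,WE,2009
GW140f,GW123m,GW007f,F,WE,2009
GW139f,GW123m,GW007f,F,WE,2010
GW347f,GW070m,GW139f,F,WE,2012
GW218m,GW161m,GW185f,M,LE,2012
GW242f,GW161m,GW185f,F,LE,2012
GW163f,GW161m,GW185f,F,LE,2013
GW233m,GW237m,GW196f,M,GKL,2012
GW257f,GW237m,GW196f,F,GKL,2012
GW323f,GW237m,GW196f,F,GKL,2013
GW333m,GW237m,GW196f,M,GKL,2013
GW111m,GW104m,GW056f,M,KH,2011
GW404m,GW104m,GW056f,M,KH,2012
GW293f,GW104m,GW056f,F,KH,2012
GW250m,GW207m,GW140f,M,SPJ,2012
GW349m,GW207m,GW140f,M,SPJ,2013
GW149m,GW207m,GW140f,M,SPJ,2013
GW351f,GW207m,GW140f,F,SPJ,2013
GW263f,GW213m,GW214f,F,MU,2012
GW339m,GW213m,GW214f,M,MU,2013
GW098f,GW037m,GW058f,F,SP,2011
GW169f,GW037m,GW058f,F,SP,2011
GW283m,GW037m,GW058f,M,SP,2012
GW277f,GW037m,GW058f,F,SP,2013
GW566m,GW037m,GW058f,M,SP,2013
GW306f,GW111m,GW245f,F,GR,2013
GW367m,GW188m,GW191f,M,BE,2013
GW599m,GW294m,GW112f,M,RT,2014
GW497f,GW208m,GW340f,F,CLH,2013
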