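sample_id,depth,temperature,o2,no3,no2,po4,dfe,dcu
s01,15,23.78,216.32929125816,2.02540494317413,0.0529615903862011,0.400843669473558,0.0956556845208352,1.03084070471581
s02,25,23,215.589249226537,4.02804150091363,0.054338514702719,0.507140992430799,0.122787194066151,1.25383997282246
s03,30,22.63,202,4.92438827045683,0.101465146824768,0.509765210112966,0.150867833536334,1.41185137477936
s04,55,20.85,148.750388201902,14.8535995503596,0.298359835525982,1.26780320129089,0.296549518238441,1.3316279321746
s05,70,19.87,72.8771433457399,22.729388532433,1.00119560948232,1.80999882655644,0.520205937095313,1.3908199715754
s06,85,18.95,19.8799216736908,20.3433590923891,2.95415599720363,2.154314633831,0.838019128281173,1.13097398840822
s07,100,18.08,6.25298159627482,15.7835266440165,5.46421475226306,2.63477014308307,1.31713363528489,1.35599295346998
s08,125,16.74,3.18394268061042,19.1546495227984,5.16820464611518,2.44889747553104,1.58048130294193,1.52583610045258
s09,200,13.44,1.89377953656881,24.0188808145146,2.10572583202992,2.7316147790585,1.67186965139942,1.2472976537561
s10,250,11.73,0.981419172190702,26.3460915571494,1.5985629152528,3.06370033967056,1.88446876593338,1.10490262442268
s11,300,10.33,1.43168792632742,29.090498006629,0.96680317384459,3.3027649573557,1.97178087937435,1.10114609019831
s12,500,6.84,8.01329795310965,34.6105431318095,0.196451312586155,3.23130381357774,1.16991176855808,1.28407744939905
s13,700,5.28,20.1224933005638,37.8388130757946,0.106211633281359,2.89665964086681,1.06110478373367,1.33412027427694
s14,850,4.7,39.818618042046,38.9978379692842,0.0484050493693084,3.2461295213826,0.943905997872014,1.45820043620653
s15,1000,4.38,44.397691710752,37.8824561989679,0.0477352403033295,3.22411557157316,0.855743527409747,1.50083817149745
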