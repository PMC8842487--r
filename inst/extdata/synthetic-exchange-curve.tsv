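time_s	F
5.1444556625957365e-12	1.0043733883347730e+00
5.5204621293763793e-12	9.9452268649968634e-01
5.9239507774281952e-12	9.9897805980281384e-01
6.3569302697773292e-12	1.0001309720902720e+00
6.8215560819286284e-12	9.9877955822487774e-01
7.3201412323384558e-12	9.9600575707657202e-01
7.8551677971739357e-12	1.0038580221968429e+00
8.4292992666818900e-12	9.9557625880290412e-01
9.0453938046805909e-12	1.0058751403387900e+00
9.7065184771831353e-12	9.9518644044076099e-01
1.0415964520985816e-11	1.0017240457713434e+00
1.1177263728232258e-11	1.0063144673440692e+00
1.1994206028519764e-11	9.8759948058315805e-01
1.2870858356075688e-11	9.9279251795404866e-01
1.3811584895928983e-11	9.9314179205326536e-01
1.4821068809867328e-11	9.9658846809112289e-01
1.5904335550337032e-11	9.9156527055443733e-01
1.7066777878347804e-11	9.7925870473975052e-01
1.8314182709927205e-11	9.7986885695262482e-01
1.9652759924773027e-11	9.9817688126908188e-01
2.1089173280520284e-11	9.8952232791564054e-01
2.2630573586521191e-11	9.8160146434280748e-01
2.4284634302284869e-11	9.8907341191157783e-01
2.6059589737794503e-11	9.9540313534214453e-01
2.7964276045872651e-11	9.9817357061081691e-01
3.0008175210664311e-11	9.8588353325326084e-01
3.2201462251222403e-11	9.8605765154284786e-01
3.4555055875186831e-11	9.7780561537453359e-01
3.7080672834723585e-11	9.8816819538620781e-01
3.9790886255320618e-11	9.8188245825594322e-01
4.2699188227814467e-11	9.8654252601694292e-01
4.5820056975246146e-11	9.8694017098727771e-01
4.9169028928919664e-11	9.8770990159406757e-01
5.2762776072474567e-11	9.7857574612005804e-01
5.6619188939009063e-11	9.8319872527332774e-01
6.0757465674433721e-11	9.7111011872982811e-01
6.5198207610435353e-11	9.7476186264356235e-01
6.9963521822835646e-11	9.7338661826497996e-01
7.5077131185903342e-11	9.6449541478021039e-01
8.0564492470497643e-11	9.7564102874393943e-01
8.6452923073964587e-11	9.7535347368997871e-01
9.2771737012677416e-11	9.7135086246949343e-01
9.9552390854223180e-11	9.7574979758899016e-01
1.0682864031572146e-10	9.6709906956289726e-01
1.1463670830786095e-10	9.6263624562487904e-01
1.2301546526121624e-10	9.7035895170672926e-01
1.3200662263255033e-10	9.6282800662982337e-01
1.4165494055442528e-10	9.7276926862554958e-01
1.5200845066185158e-10	9.6202980487443324e-01
1.6311869520526032e-10	9.6607885802851146e-01
1.7504098364015658e-10	9.6299997714412466e-01
1.8783466797082060e-10	9.5603788773927900e-01
2.0156343821878638e-10	9.6638030556996413e-01
2.1629563948700829e-10	9.6023945820714962e-01
2.3210461219813434e-10	9.5597661646154175e-01
2.4906905720067538e-10	9.5539381734953754e-01
2.6727342756065981e-10	9.5587198555023123e-01
2.8680834898920375e-10	9.5137122420423392e-01
3.0777107099898233e-10	9.3438596246665018e-01
3.3026595103556849e-10	9.4918878874858559e-01
3.5440497399376701e-10	9.4432551961015343e-01
3.8030830970521596e-10	9.4547024666769464e-01
4.0810491117255790e-10	9.4582139318814795e-01
4.3793315652833638e-10	9.4826558836562258e-01
4.6994153791444955e-10	9.3597216258119165e-01
5.0428940071156334e-10	9.4445075356762542e-01
5.4114773679853785e-10	9.3793497662389558e-01
5.8070003579090639e-10	9.3975478831542592e-01
6.2314319849608552e-10	9.3746176534788284e-01
6.6868851713270850e-10	9.3474820609188036e-01
7.1756272719383776e-10	9.2420419511439855e-01
7.7000913619049228e-10	9.2723553637874123e-01
8.2628883489465299e-10	9.2906183250087782e-01
8.8668199711159924e-10	9.1942585292580870e-01
9.5148927445213943e-10	9.1972033716794988e-01
1.0210332930482539e-09	9.2357255693264506e-01
1.0956602596631760e-09	9.2273391073308031e-01
1.1757416851914974e-09	9.1942988445480334e-01
1.2616762341292820e-09	9.1089298876533031e-01
1.3538917092212991e-09	9.0802676124044257e-01
1.4528471811654471e-09	9.1928611561768891e-01
1.5590352739765337e-09	9.1120233971265729e-01
1.6729846173864749e-09	9.0853841060478069e-01
1.7952624784895650e-09	9.0566858647347193e-01
1.9264775857338019e-09	8.9847169462808674e-01
2.0672831593167558e-09	9.0566700057101690e-01
2.2183801630719890e-09	8.9967836649971944e-01
2.3805207940347086e-09	8.9800063838778543e-01
2.5545122270585874e-09	9.0172471765995810e-01
2.7412206331253248e-09	8.9930349153263411e-01
2.9415754913510122e-09	9.0028475718525880e-01
3.1565742161555339e-09	8.8906556218298516e-01
3.3872871226302004e-09	8.9281289895517213e-01
3.6348627548223749e-09	8.9462362260826733e-01
3.9005336034625151e-09	8.8021291131353874e-01
4.1856222415978804e-09	8.7955318810913607e-01
4.4915479086776098e-09	8.7627985667583119e-01
4.8198335758662953e-09	8.7271452898341217e-01
5.1721135277587889e-09	8.7847270616237083e-01
5.5501414982398851e-09	8.7939059691845956e-01
5.9557994009912166e-09	8.8017015586326575e-01
6.3911066981078633e-09	8.7741813329579266e-01
6.8582304534637857e-09	8.6519493598047892e-01
7.3594961208742238e-09	8.7745672921948048e-01
7.8973991207611954e-09	8.6286964282389111e-01
8.4746172629534559e-09	8.6470514710953172e-01
9.0940240774644631e-09	8.6002418439742223e-01
9.7587031196122087e-09	8.5946425968108298e-01
1.0471963320695405e-08	8.5893892251596260e-01
1.1237355460645234e-08	8.5649573479190566e-01
1.2058689844657328e-08	8.5365496827350984e-01
1.2940055271802571e-08	8.5217819225666680e-01
1.3885839390047204e-08	8.4704316823829751e-01
1.4900750539014260e-08	8.4475495431885816e-01
1.5989841189224628e-08	8.3674730628310678e-01
1.7158533094503997e-08	8.4088665549225716e-01
1.8412644282770676e-08	8.3794684025246258e-01
1.9758418019570678e-08	8.5169481226701294e-01
2.1202553888547251e-08	8.2901053974083028e-01
2.2752241143570974e-08	8.3410038402366982e-01
2.4415194498565720e-08	8.2349259123865626e-01
2.6199692533200505e-08	8.2110485774074971e-01
2.8114618905639641e-08	8.2652227575089843e-01
3.0169506577518306e-08	8.1829799236924128e-01
3.2374585271306526e-08	8.2059003071481362e-01
3.4740832396315366e-08	8.1570566926001886e-01
3.7280027696866684e-08	8.1195006785464086e-01
4.0004811894678434e-08	8.0198330720847300e-01
4.2928749617401954e-08	8.0298052572394496e-01
4.6066396926584062e-08	8.0690045973481761e-01
4.9433373781223847e-08	8.0563155812082388e-01
5.3046441797665302e-08	7.9700162907175653e-01
5.6923587692934054e-08	7.9600989653704113e-01
6.1084112826918511e-08	7.9802653296122528e-01
6.5548729289156994e-08	7.9585953812759513e-01
7.0339663008574463e-08	7.7925396852459994e-01
7.5480764399474625e-08	7.8004733299838036e-01
8.0997627094609271e-08	7.8233340617325386e-01
8.6917715356405004e-08	7.6944765503335755e-01
9.3270500800631968e-08	7.6676178415925045e-01
1.0008760911315873e-07	7.6155599652238848e-01
1.0740297749018389e-07	7.5222022650511888e-01
1.1525302358571781e-07	7.4878996203929649e-01
1.2367682680737625e-07	7.4487434174661116e-01
1.3271632286302309e-07	7.3658225380928810e-01
1.4241651252675642e-07	7.3743641917342340e-01
1.5282568566352883e-07	7.2223379540917476e-01
1.6399566162764858e-07	7.1475452099054115e-01
1.7598204723192340e-07	7.1215694019587905e-01
1.8884451357167874e-07	6.9456930097820657e-01
2.0264709308174685e-07	6.9020520594955626e-01
2.1745849830524745e-07	6.7253741870460060e-01
2.3335246396106690e-07	6.7529308575125413e-01
2.5040811401293040e-07	6.5647023628243117e-01
2.6871035556742382e-07	6.4303956005993745e-01
2.8835030156188491e-07	6.2582310502637961e-01
3.0942572434640433e-07	6.1763842842520100e-01
3.3204154241797670e-07	5.9829352565679872e-01
3.5631034272988105e-07	5.8312262538606185e-01
3.8235294117647085e-07	5.7451834562975712e-01
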