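(t08:0.09607554971,t07:0.1479912506,(((((t05:0.2928299959,t06:0.1480100028):0.03737423222,t03:0.1481235254):0.1033851263,OUT:0.05915412802):0.192128003,(t02:0.04045152271,t04:0.04788575404):0.1432286858):0.05550008997,t01:0.09051682425):0.03751097768);
(t08:0.2090150272,t07:0.246977002,(((((t03:0.1960735367,t06:0.159769948):0.03230872546,t05:0.254451649):0.09541361822,(t02:0.03551870888,t04:0.04350167786):0.134917805):0.03024915029,OUT:0.1596555259):0.1065072878,t01:0.07531686435):0.01349903403);
(t06:0.1998286685,t05:0.2115957953,(((((t01:0.07132066631,t07:0.2327781648):0.0302058741,t08:0.18278814):0.1024169016,(t02:0.08231471075,t04:0.04449253678):0.1833137819):0.1634943514,OUT:0.2041919194):0.05363923802,t03:0.2384810562):0.02791481389);
(t08:0.1525465575,t07:0.2168108064,(((((t03:0.161180412,t06:0.1555237578):0.0531560067,t05:0.1716111262):0.1356448123,OUT:0.1405454636):0.0623542626,(t02:0.05415575285,t04:0.05316987988):0.1548403525):0.05669073249,t01:0.1050795024):0.0147575451);
(t06:0.1942403281,t03:0.1224638417,(((((t01:0.09082424671,t08:0.0976615745):0.01578494329,t07:0.2133059626):0.07793455882,(t02:0.02968191572,t04:0.03104488118):0.1862325901):0.08588990018,OUT:0.1903303212):0.05434721637,t05:0.2059040071):0.006218637319);
(t07:0.1894621486,t01:0.1146366825,(((((t03:0.1314545839,t06:0.2243889008):0.1136933221,OUT:0.08715701976):0.03781495011,t05:0.2125353808):0.1523281315,(t02:0.04320536098,t04:0.04513191576):0.1967936409):0.121073263,t08:0.1445304112):0.02785208717);
((t02:0.02484195685,t04:0.02690269676):0.1129541325,((t07:0.141304442,t08:0.138202022):0.03240089317,t01:0.1134500341):0.1015549903,(((t03:0.1481157067,t06:0.1685884631):0.03482375191,t05:0.1495084029):0.08549466081,OUT:0.1409032489):0.02395144581);
(t08:0.1581452118,t01:0.09754972843,(((((t03:0.195916151,t06:0.1734412128):0.0779900281,t05:0.1522389667):0.1018580958,OUT:0.1280432106):0.1303891289,(t02:0.06460462595,t04:0.0237326508):0.138337728):0.09518753104,t07:0.1435964906):0.02066122813);
(OUT:0.1788236337,((t07:0.2157012446,t08:0.25575525):0.05730249247,t01:0.1635865501):0.1158144113,(((t03:0.1952592832,t06:0.1605842015):0.06824179614,t05:0.2293842033):0.1233431407,(t02:0.060750233,t04:0.02758704375):0.2231278339):0.04516596257);
(t08:0.1789287829,t01:0.07676615737,(((((t03:0.1395533556,t06:0.1399531084):0.05543063799,t05:0.1674165543):0.1500557326,OUT:0.1900113947):0.0792013347,(t02:0.06006787081,t04:0.03770349258):0.1878366086):0.07433363858,t07:0.1408347958):0.01990837051);
(t08:0.1378530459,t01:0.07237342799,(((((t03:0.1607546176,t06:0.08331218271):0.0325377484,t05:0.1564664844):0.04773980285,OUT:0.08889381665):0.1748857731,(t02:0.02162279439,t04:0.07614856901):0.1549935143):0.04797393892,t07:0.1552574666):0.02582885154);
(t08:0.1574876228,t07:0.172037372,(((((t03:0.1498093089,t06:0.179715686):0.08213073205,t05:0.1963544821):0.05970886927,OUT:0.1680394503):0.1036041392,(t02:0.07717296626,t04:0.05956820134):0.1359559033):0.05968092484,t01:0.09099046852):0.04214737691);
(t01:0.1335640675,(t07:0.2033786827,t08:0.1391901192):0.04506322542,((((t03:0.06895159894,t06:0.2227502557):0.06606335567,t05:0.1853575578):0.07753215041,OUT:0.1492720223):0.1058586944,(t02:0.03319207073,t04:0.03662574657):0.15632296):0.02184761659);
(t07:0.2112305103,t01:0.06827595362,(((((t03:0.1367324658,t06:0.1799717041):0.04096091277,t05:0.1978253199):0.1473386222,OUT:0.2058305874):0.059463945,(t02:0.03674203589,t04:0.04227835085):0.2133314625):0.06345731595,t08:0.168276096):0.005563681058);
(t08:0.1607885976,t07:0.1950548871,(((((t03:0.09386704296,t06:0.1054103313):0.05704956775,t05:0.1474105762):0.0619606284,OUT:0.09644532808):0.08924355174,(t02:0.03725251139,t04:0.05108476535):0.1079966994):0.04659945274,t01:0.0894984119):0.0304801886);
(t06:0.2619219893,t03:0.1074353745,(((((t07:0.1839225611,t08:0.1456024337):0.03797658124,t01:0.121033591):0.1148135555,(t02:0.02682798601,t04:0.01604082437):0.2045644052):0.0736790864,OUT:0.1631660851):0.06860134754,t05:0.2203655187):0.03956467404);
(t08:0.1460800799,t07:0.1096148604,(((((t03:0.1244139326,t06:0.272724385):0.1195952068,t05:0.2275683466):0.05313634285,OUT:0.1565140362):0.1081088857,(t02:0.01924828556,t04:0.05977210118):0.1827311935):0.09945513806,t01:0.07615336573):0.02895987121);
(t06:0.2648228798,((((t07:0.1931392487,t08:0.1235649211):0.04823624315,t01:0.1101158418):0.100095832,(t02:0.06702959906,t04:0.06971156854):0.1896084394):0.04364072051,OUT:0.1755481225):0.1554852329,(t03:0.2754057837,t05:0.1960507109):0.02005073167);
(t08:0.1708748019,t07:0.1849686828,(((((t03:0.2308236692,t06:0.1663146484):0.02174924487,t05:0.1561724975):0.1320482509,OUT:0.1361803489):0.1033627239,(t02:0.06438828326,t04:0.06241896427):0.2053074517):0.07709279878,t01:0.1746010306):0.04461554462);
(t08:0.1380600734,(t02:0.05365223347,t04:0.02536815328):0.1787518395,((t01:0.09448095284,t07:0.1850255111):0.03367321361,(((t03:0.128329334,t06:0.1883748358):0.04815924261,t05:0.1844044289):0.06213660801,OUT:0.1087500238):0.09474910629):0.005755998478);
(t08:0.1196231729,t07:0.1970809969,(((((t03:0.1601136248,t06:0.1315882298):0.03821418137,t05:0.3033512413):0.0644032136,OUT:0.1169338921):0.2218310883,(t02:0.07734010222,t04:0.03966308414):0.1532021552):0.06349707672,t01:0.08117275021):0.02319347453);
((((t03:0.1786758688,t06:0.1254229623):0.03279302464,t05:0.2197111828):0.06761352144,OUT:0.1274458193):0.1990924259,(t02:0.0818908262,t04:0.0158805372):0.09116202831,((t07:0.1476134541,t08:0.1949553477):0.05266270221,t01:0.1252590401):0.04121844451);
(OUT:0.1859287072,(t03:0.1325694138,t06:0.1349367941):0.1364664355,((((t07:0.2562187077,t08:0.1409196099):0.05246900446,t01:0.07339375065):0.06523453382,(t02:0.06311967201,t04:0.03465169139):0.1200002389):0.08267442242,t05:0.2518766451):0.04989296347);
(t08:0.1555814937,t07:0.1361203609,(((((t03:0.2087243998,t06:0.202700064):0.09242512791,t05:0.165586902):0.02682716295,OUT:0.1981539894):0.1315402855,(t02:0.03284566797,t04:0.06492569543):0.1937004278):0.08119511338,t01:0.09870299701):0.03495253965);
(t06:0.2610182896,t03:0.1949737395,(((((t07:0.2254802172,t08:0.09122395267):0.02110929129,t01:0.1024919188):0.1490882245,(t02:0.03209984502,t04:0.01964480859):0.1570888293):0.05487379796,OUT:0.1181058857):0.03839422053,t05:0.1658056914):0.03276346741);
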