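"name","phase","model","predicted","re_percent"
"acetone",DB-210,individual,764.8,-3.54
"2-butanone",DB-210,individual,869.9,-1.38
"3-methyl-2-butanone",DB-210,individual,943.8,0.05
"3-pentanone",DB-210,individual,970.2,0.98
"3,3-dimethyl-2-butanone",DB-210,individual,991.6,-0.04
"4-methyl-2-pentanone",DB-210,individual,1004.2,-2.23
"2,4-dimethyl-3-pentanone",DB-210,individual,1084.2,4.4
"2-hexanone",DB-210,individual,1079,-0.23
"4-heptanone",DB-210,individual,1126.9,-0.67
"5-methyl-2-hexanone",DB-210,individual,1122.9,-3.31
"2-heptanone",DB-210,individual,1186.6,0.19
"2-methyl-3-heptanone",DB-210,individual,1173.2,-1.61
"5-methyl-3-heptanone",DB-210,individual,1172.2,14.15
"3-octanone",DB-210,individual,1252.3,-0.25
"5-nonanone",DB-210,individual,1310,-2.43
"acrolein",DB-210,individual,770.1,3.55
"isobutanal",DB-210,individual,839.9,4.5
"butanal",DB-210,individual,860.5,2.06
"isovaleraldehyde",DB-210,individual,919.1,0.69
"2-methylbutanal",DB-210,individual,893.9,-2.12
"valeraldehyde",DB-210,individual,966.8,1.36
"2-butenal",DB-210,individual,897.7,-7.19
"2-ethylbutyraldehyde",DB-210,individual,1000.9,-0.86
"hexanal",DB-210,individual,1113.6,5.13
"heptanal",DB-210,individual,1149.4,-1.14
"octanal",DB-210,individual,1240.9,-1.94
"2-pentanone",DB-210,individual,979.3,0.55
"3-methyl-2-pentanone",DB-210,individual,1023.7,-1.2
"3-hexanone",DB-210,individual,1043.9,-0.43
"3-heptanone",DB-210,individual,1132.8,-1.8
"propanal",DB-210,individual,760,2.79
"trimethylacetaldehyde",DB-210,individual,876.4,4.13
"3,3-dimethylbutanal",DB-210,individual,943.3,-3.59
"2-ethylhexanal",DB-210,individual,1109.1,-7.99
"acetone",DB-210,ensemble,792.9,0
"2-butanone",DB-210,ensemble,872.6,-1.08
"3-methyl-2-butanone",DB-210,ensemble,934.1,-0.98
"3-pentanone",DB-210,ensemble,959.3,-0.16
"3,3-dimethyl-2-butanone",DB-210,ensemble,982.8,-0.93
"4-methyl-2-pentanone",DB-210,ensemble,995.6,-3.07
"2,4-dimethyl-3-pentanone",DB-210,ensemble,1077.8,3.78
"2-hexanone",DB-210,ensemble,1075.6,-0.55
"4-heptanone",DB-210,ensemble,1122.3,-1.08
"5-methyl-2-hexanone",DB-210,ensemble,1118.4,-3.69
"2-heptanone",DB-210,ensemble,1185.7,0.12
"2-methyl-3-heptanone",DB-210,ensemble,1164.1,-2.37
"5-methyl-3-heptanone",DB-210,ensemble,1184.1,15.31
"3-octanone",DB-210,ensemble,1254,-0.12
"5-nonanone",DB-210,ensemble,1325.4,-1.28
"acrolein",DB-210,ensemble,776.1,4.36
"isobutanal",DB-210,ensemble,839.3,4.43
"butanal",DB-210,ensemble,859.3,1.92
"isovaleraldehyde",DB-210,ensemble,908.1,-0.51
"2-methylbutanal",DB-210,ensemble,890.2,-2.53
"valeraldehyde",DB-210,ensemble,959.3,0.58
"2-butenal",DB-210,ensemble,912.7,-5.63
"2-ethylbutyraldehyde",DB-210,ensemble,989.8,-1.96
"hexanal",DB-210,ensemble,1133.3,6.99
"heptanal",DB-210,ensemble,1148.4,-1.23
"octanal",DB-210,ensemble,1238.5,-2.13
"2-pentanone",DB-210,ensemble,978.7,0.49
"3-methyl-2-pentanone",DB-210,ensemble,1021.1,-1.45
"3-hexanone",DB-210,ensemble,1042.3,-0.58
"3-heptanone",DB-210,ensemble,1139.2,-1.25
"propanal",DB-210,ensemble,764.3,3.37
"trimethylacetaldehyde",DB-210,ensemble,900.8,7.03
"3,3-dimethylbutanal",DB-210,ensemble,938.1,-4.12
"2-ethylhexanal",DB-210,ensemble,1129.7,-6.28
"acetone",HP-Innowax,individual,877.3,5.07
"2-butanone",HP-Innowax,individual,917.5,-0.25
"3-methyl-2-butanone",HP-Innowax,individual,951.8,0.25
"3-pentanone",HP-Innowax,individual,972.3,-2.47
"3,3-dimethyl-2-butanone",HP-Innowax,individual,904.8,-6.58
"4-methyl-2-pentanone",HP-Innowax,individual,1041.4,1.58
"2,4-dimethyl-3-pentanone",HP-Innowax,individual,971.1,-4.31
"2-hexanone",HP-Innowax,individual,1100.2,0.27
"4-heptanone",HP-Innowax,individual,1148,0.75
"5-methyl-2-hexanone",HP-Innowax,individual,1139.5,-1.44
"2-heptanone",HP-Innowax,individual,1211.3,1.3
"2-methyl-3-heptanone",HP-Innowax,individual,1201.5,1.93
"5-methyl-3-heptanone",HP-Innowax,individual,1166.2,-2.82
"3-octanone",HP-Innowax,individual,1262.5,-0.24
"5-nonanone",HP-Innowax,individual,1345.1,0.82
"acrolein",HP-Innowax,individual,853,-1.61
"isobutanal",HP-Innowax,individual,836.8,0.77
"butanal",HP-Innowax,individual,937.4,4.76
"isovaleraldehyde",HP-Innowax,individual,951.3,1.63
"2-methylbutanal",HP-Innowax,individual,897.2,-3.65
"valeraldehyde",HP-Innowax,individual,1037.6,3.96
"2-butenal",HP-Innowax,individual,953.8,-10.15
"2-ethylbutyraldehyde",HP-Innowax,individual,1146.8,12.65
"hexanal",HP-Innowax,individual,1135.8,3.41
"heptanal",HP-Innowax,individual,1207.7,0.68
"octanal",HP-Innowax,individual,1265.8,-2.54
"2-pentanone",HP-Innowax,individual,1011,1.49
"3-methyl-2-pentanone",HP-Innowax,individual,1021.6,-1.19
"3-hexanone",HP-Innowax,individual,1055.9,-1.13
"3-heptanone",HP-Innowax,individual,1154.8,-1.06
"propanal",HP-Innowax,individual,855.9,5.82
"trimethylacetaldehyde",HP-Innowax,individual,779.7,-5.22
"3,3-dimethylbutanal",HP-Innowax,individual,885.9,-8.54
"2-ethylhexanal",HP-Innowax,individual,1189.8,-0.67
"acetone",HP-Innowax,ensemble,879.1,5.28
"2-butanone",HP-Innowax,ensemble,915.6,-0.46
"3-methyl-2-butanone",HP-Innowax,ensemble,948.4,-0.11
"3-pentanone",HP-Innowax,ensemble,968,-2.9
"3,3-dimethyl-2-butanone",HP-Innowax,ensemble,893.7,-7.72
"4-methyl-2-pentanone",HP-Innowax,ensemble,1033.6,0.82
"2,4-dimethyl-3-pentanone",HP-Innowax,ensemble,1010.7,-0.4
"2-hexanone",HP-Innowax,ensemble,1085.6,-1.06
"4-heptanone",HP-Innowax,ensemble,1156.6,1.51
"5-methyl-2-hexanone",HP-Innowax,ensemble,1148.8,-0.63
"2-heptanone",HP-Innowax,ensemble,1183.5,-1.03
"2-methyl-3-heptanone",HP-Innowax,ensemble,1210.8,2.72
"5-methyl-3-heptanone",HP-Innowax,ensemble,1190.4,-0.81
"3-octanone",HP-Innowax,ensemble,1257.1,-0.66
"5-nonanone",HP-Innowax,ensemble,1361.4,2.05
"acrolein",HP-Innowax,ensemble,855,-1.38
"isobutanal",HP-Innowax,ensemble,877.7,5.7
"butanal",HP-Innowax,ensemble,927.7,3.68
"isovaleraldehyde",HP-Innowax,ensemble,963.9,2.98
"2-methylbutanal",HP-Innowax,ensemble,920.6,-1.14
"valeraldehyde",HP-Innowax,ensemble,1007.9,0.98
"2-butenal",HP-Innowax,ensemble,955.2,-10.01
"2-ethylbutyraldehyde",HP-Innowax,ensemble,1112.5,9.28
"hexanal",HP-Innowax,ensemble,1156,5.25
"heptanal",HP-Innowax,ensemble,1176.9,-1.89
"octanal",HP-Innowax,ensemble,1249.2,-3.82
"2-pentanone",HP-Innowax,ensemble,993,-0.32
"3-methyl-2-pentanone",HP-Innowax,ensemble,1008.8,-2.43
"3-hexanone",HP-Innowax,ensemble,1058.4,-0.9
"3-heptanone",HP-Innowax,ensemble,1158,-0.79
"propanal",HP-Innowax,ensemble,856.7,5.92
"trimethylacetaldehyde",HP-Innowax,ensemble,840.5,2.18
"3,3-dimethylbutanal",HP-Innowax,ensemble,942.6,-2.68
"2-ethylhexanal",HP-Innowax,ensemble,1240.2,3.54
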