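name,smiles,group,ri_db210,ri_innowax
acetone,CC(C)=O,I,792.9,835.0
2-butanone,CCC(C)=O,I,882.1,919.8
3-methyl-2-butanone,CC(C)C(C)=O,I,943.3,949.4
3-pentanone,CCC(=O)CC,I,960.8,996.9
"3,3-dimethyl-2-butanone",CC(=O)C(C)(C)C,I,992.0,968.5
4-methyl-2-pentanone,CC(C)CC(C)=O,I,1027.1,1025.2
"2,4-dimethyl-3-pentanone",CC(C)C(=O)C(C)C,I,1038.5,1014.8
2-hexanone,CCCCC(C)=O,I,1081.5,1097.2
4-heptanone,CCCC(=O)CCC,I,1134.5,1139.4
5-methyl-2-hexanone,CC(C)CCC(C)=O,I,1161.3,1156.1
2-heptanone,CCCCCC(C)=O,I,1184.3,1195.8
2-methyl-3-heptanone,CCCCC(=O)C(C)C,I,1192.4,1178.7
5-methyl-3-heptanone,CCC(=O)CC(C)CC,I,1026.9,1200.1
3-octanone,CCCCCC(=O)CC,I,1255.5,1265.5
5-nonanone,CCCCC(=O)CCCC,I,1342.6,1334.1
acrolein,C=CC=O,I,743.7,867.0
isobutanal,CC(C)C=O,I,803.7,830.4
butanal,CCCC=O,I,843.1,894.8
isovaleraldehyde,CC(C)CC=O,I,912.8,936.0
2-methylbutanal,CCC(C)C=O,I,913.3,931.2
valeraldehyde,CCCCC=O,I,953.8,998.1
2-butenal,CC=CC=O,I,967.2,1061.5
2-ethylbutyraldehyde,CCC(CC)C=O,I,1009.6,1018.0
hexanal,CCCCCC=O,I,1059.3,1098.3
heptanal,CCCCCCC=O,I,1162.7,1199.6
octanal,CCCCCCCC=O,I,1265.4,1298.8
2-pentanone,CCCC(C)=O,II,973.9,996.2
3-methyl-2-pentanone,CCC(C)C(C)=O,II,1036.1,1033.9
3-hexanone,CCCC(=O)CC,II,1048.4,1068.0
3-heptanone,CCCCC(=O)CC,II,1153.6,1167.2
propanal,CCC=O,II,739.4,808.8
trimethylacetaldehyde,CC(C)(C)C=O,II,841.6,822.6
"3,3-dimethylbutanal",CC(C)(C)CC=O,II,978.4,968.6
2-ethylhexanal,CCCCC(CC)C=O,II,1205.4,1197.8
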