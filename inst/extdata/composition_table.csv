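code,name,group,energy_kcal_100g,protein_g_100g,fat_g_100g,carb_g_100g
A001,arroz pilado,cereals,358,7.8,0.7,81.7
A002,avena hojuelas,cereals,374,13.3,6.5,72.4
A003,fideos tallarin,cereals,353,10.5,1.3,75.4
A004,harina de trigo,cereals,354,10.5,1.3,74.8
A005,quinua,cereals,343,13.6,5.8,66.6
A006,maiz amarillo seco,cereals,349,8.4,4.3,72.2
A007,galleta de agua,cereals,435,9.5,11.0,71.3
B001,azucar rubia,sugars,380,0.0,0.0,98.0
B002,chancaca,sugars,352,0.4,0.1,90.8
B003,mermelada de fruta,sugars,246,0.4,0.1,63.4
C001,conserva de pescado en agua,meats,105,23.6,1.0,0.0
C002,atun en conserva en aceite,meats,186,24.0,10.0,0.0
C003,anchoveta en salsa de tomate,meats,158,17.5,9.0,1.5
C004,charqui de res,meats,348,59.8,10.5,0.0
C005,grated de pescado,meats,130,20.0,5.4,0.0
C006,mortadela,meats,247,12.0,20.0,3.0
D001,aceite vegetal,oils,884,0.0,100.0,0.0
D002,aceite de soya,oils,884,0.0,100.0,0.0
D003,aceite de oliva,oils,884,0.0,100.0,0.0
E001,leche evaporada entera,dairy,134,6.3,7.6,9.9
E002,leche en polvo entera,dairy,496,26.3,26.7,38.4
E003,queso fresco de vaca,dairy,234,17.5,16.5,3.3
F001,frijol canario,legumes,330,21.8,1.8,61.2
F002,lenteja,legumes,338,23.5,1.3,60.8
F003,arveja seca partida,legumes,335,21.7,1.9,61.1
F004,garbanzo,legumes,364,19.3,6.0,61.0
F005,haba seca,legumes,334,25.1,1.5,58.3
G001,platano de seda,fruits,92,1.0,0.3,23.0
G002,naranja,fruits,47,0.9,0.1,11.8
G003,manzana,fruits,52,0.3,0.2,13.8
G004,mandarina,fruits,53,0.8,0.2,13.3
H001,huevo de gallina,eggs,143,12.6,9.5,0.7
H002,huevo de codorniz,eggs,158,13.1,11.1,0.4
I001,cebolla de cabeza,vegetables,40,1.1,0.1,9.3
I002,zanahoria,vegetables,41,0.9,0.2,9.6
I003,tomate,vegetables,18,0.9,0.2,3.9
I004,zapallo macre,vegetables,26,1.0,0.1,6.5
J001,papa blanca,tubers,97,2.1,0.1,22.3
J002,camote amarillo,tubers,116,1.2,0.2,27.6
J003,yuca blanca,tubers,160,0.8,0.2,39.3
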