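food_name,wholesale_price_per_kg,retail_price_per_kg
arroz pilado,2.8,3.6
avena hojuelas,5.0,6.4
fideos tallarin,3.6,4.6
harina de trigo,2.6,3.4
quinua,9.0,12.0
maiz amarillo seco,2.4,3.2
galleta de agua,7.0,9.0
azucar rubia,2.4,3.2
chancaca,4.0,5.0
mermelada de fruta,8.0,10.0
conserva de pescado en agua,16.0,20.0
atun en conserva en aceite,20.0,26.0
anchoveta en salsa de tomate,12.0,15.0
charqui de res,38.0,46.0
grated de pescado,14.0,18.0
mortadela,11.0,14.0
aceite vegetal,6.4,8.0
aceite de soya,6.0,7.6
aceite de oliva,28.0,36.0
leche evaporada entera,8.4,10.4
leche en polvo entera,24.0,30.0
queso fresco de vaca,16.0,20.0
frijol canario,6.4,8.0
lenteja,5.2,6.8
arveja seca partida,4.4,5.6
garbanzo,6.8,8.8
haba seca,4.8,6.0
platano de seda,1.6,2.4
naranja,1.4,2.0
manzana,2.4,3.4
mandarina,1.8,2.6
huevo de gallina,4.8,6.0
huevo de codorniz,12.0,16.0
cebolla de cabeza,1.2,2.0
zanahoria,1.0,1.8
tomate,1.6,2.6
zapallo macre,1.0,1.6
papa blanca,0.9,1.5
camote amarillo,0.8,1.4
yuca blanca,1.2,1.8
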