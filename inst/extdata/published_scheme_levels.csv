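group_id,scenario,cap_ug_per_10mj,level_ug_per_10mj,level_ug_per_100g
milk,1,12,2,0.274
milk,2,25,25,0.571
milk,3,20,20,0.457
milk,4,20,20,0.457
milk,5,25,25,0.571
milk,6,25,25,0.571
milk,7,30,24,0.548
milk,8,30,25,0.571
cheese,1,12,12,1.464
cheese,2,25,0,0.000
cheese,3,20,8,0.976
cheese,4,20,16,1.952
cheese,5,25,3,0.366
cheese,6,25,3,0.366
cheese,7,30,0,0.000
cheese,8,30,0,0.000
icecream,1,12,12,1.037
icecream,2,25,25,2.161
icecream,3,20,0,0.000
icecream,4,20,0,0.000
icecream,5,25,0,0.000
icecream,6,25,0,0.000
icecream,7,30,0,0.000
icecream,8,30,0,0.000
cereals,1,12,12,1.418
cereals,2,25,15,1.773
cereals,3,20,20,2.364
cereals,4,20,20,2.364
cereals,5,25,25,2.955
cereals,6,25,25,2.955
cereals,7,30,27,3.191
cereals,8,30,28,3.309
vegetables,1,12,12,0.435
vegetables,2,25,0,0.000
vegetables,3,20,0,0.000
vegetables,4,20,0,0.000
vegetables,5,25,0,0.000
vegetables,6,25,0,0.000
vegetables,7,30,0,0.000
vegetables,8,30,0,0.000
fruit,1,12,12,0.435
fruit,2,25,0,0.000
fruit,3,20,0,0.000
fruit,4,20,0,0.000
fruit,5,25,0,0.000
fruit,6,25,0,0.000
fruit,7,30,0,0.000
fruit,8,30,0,0.000
meat,1,12,12,1.055
meat,2,25,0,0.000
meat,3,20,0,0.000
meat,4,20,0,0.000
meat,5,25,0,0.000
meat,6,25,0,0.000
meat,7,30,0,0.000
meat,8,30,0,0.000
fish,1,12,0,0.000
fish,2,25,0,0.000
fish,3,20,0,0.000
fish,4,20,0,0.000
fish,5,25,0,0.000
fish,6,25,0,0.000
fish,7,30,0,0.000
fish,8,30,0,0.000
poultry,1,12,12,0.733
poultry,2,25,25,1.528
poultry,3,20,0,0.000
poultry,4,20,0,0.000
poultry,5,25,0,0.000
poultry,6,25,0,0.000
poultry,7,30,0,0.000
poultry,8,30,0,0.000
eggs,1,12,12,0.716
eggs,2,25,0,0.000
eggs,3,20,0,0.000
eggs,4,20,0,0.000
eggs,5,25,0,0.000
eggs,6,25,0,0.000
eggs,7,30,0,0.000
eggs,8,30,0,0.000
fats,1,12,12,3.508
fats,2,25,0,0.000
fats,3,20,20,5.847
fats,4,20,20,5.847
fats,5,25,4,1.169
fats,6,25,7,2.047
fats,7,30,0,0.000
fats,8,30,0,0.000
sugar,1,12,12,2.172
sugar,2,25,25,4.525
sugar,3,20,0,0.000
sugar,4,20,0,0.000
sugar,5,25,0,0.000
sugar,6,25,0,0.000
sugar,7,30,0,0.000
sugar,8,30,0,0.000
beverages,1,12,0,0.000
beverages,2,25,0,0.000
beverages,3,20,0,0.000
beverages,4,20,0,0.000
beverages,5,25,0,0.000
beverages,6,25,0,0.000
beverages,7,30,0,0.000
beverages,8,30,0,0.000
spices,1,12,11,0.091
spices,2,25,19,0.157
spices,3,20,0,0.000
spices,4,20,0,0.000
spices,5,25,0,0.000
spices,6,25,0,0.000
spices,7,30,0,0.000
spices,8,30,0,0.000
other,1,12,12,2.717
other,2,25,25,5.660
other,3,20,0,0.000
other,4,20,0,0.000
other,5,25,0,0.000
other,6,25,0,0.000
other,7,30,0,0.000
other,8,30,0,0.000
potato,1,12,12,0.469
potato,2,25,24,0.938
potato,3,20,0,0.000
potato,4,20,0,0.000
potato,5,25,0,0.000
potato,6,25,0,0.000
potato,7,30,0,0.000
potato,8,30,0,0.000
juice,1,12,12,0.228
juice,2,25,25,0.476
juice,3,20,19,0.362
juice,4,20,0,0.000
juice,5,25,25,0.476
juice,6,25,0,0.000
juice,7,30,29,0.552
juice,8,30,0,0.000
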