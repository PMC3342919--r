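chemical_name,cas_number,toxicity_weight,carcinogen_class
"2,4-Dinitrophenol",51-28-5,500,non_carcinogen
"1,1,1-Trichloroethane",71-55-6,0.5,non_carcinogen
Methoxychlor,72-43-5,200,non_carcinogen
"1,1-Dichloroethylene",75-35-4,20,non_carcinogen
Hexachlorocyclopentadiene,77-47-4,170,non_carcinogen
Dinoseb,88-85-7,1000,non_carcinogen
"2,4-D",94-75-7,200,non_carcinogen
o-Dichlorobenzene,95-50-1,11,non_carcinogen
"1,2-Dibromo-3-chloropropane",96-12-8,5000,non_carcinogen
Styrene,100-42-5,5,non_carcinogen
Toluene,108-88-3,13,non_carcinogen
Chlorobenzene,108-90-7,50,non_carcinogen
Phenol,108-95-2,3.3,non_carcinogen
"1,2,4-Trichlorobenzene",120-82-1,100,non_carcinogen
Xylene,1330-20-7,5,non_carcinogen
Carbofuran,1563-66-2,1200,non_carcinogen
Atrazine,1912-24-9,56,non_carcinogen
Lead,7439-92-1,18000,non_carcinogen
Manganese,7439-96-5,7.1,non_carcinogen
Mercury,7439-97-6,10000,non_carcinogen
Nickel,7440-02-0,20,non_carcinogen
Thallium,7440-28-0,14000,non_carcinogen
Antimony,7440-36-0,2500,non_carcinogen
Barium,7440-39-3,5,non_carcinogen
Beryllium,7440-41-7,500,non_carcinogen
Cadmium,7440-43-9,2000,non_carcinogen
Chromium,7440-47-3,330,non_carcinogen
Copper,7440-50-8,1500,non_carcinogen
Selenium,7782-49-2,200,non_carcinogen
Chlorine,7782-50-5,10,non_carcinogen
Lindane,58-89-9,110000,carcinogen
Benzene,71-43-2,55000,carcinogen
"1,1,2-Trichloroethane",79-00-5,5700,carcinogen
Ethylbenzene,100-41-4,1100,carcinogen
p-Dichlorobenzene,106-46-7,2400,carcinogen
Di(2-ethylhexyl) phthalate,117-81-7,14000,carcinogen
Polychlorinated biphenyls,1336-36-3,2000000,carcinogen
Arsenic,7440-38-2,1500000,carcinogen
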