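class,order,family,species,n_collected,n_detected,n_positive
Insecta,Diptera,Syrphidae,Sphaerophoria rueppeuii,33,33,0
Insecta,Diptera,Syrphidae,Eupeodes luniger,17,16,0
Insecta,Diptera,Syrphidae,Scaeva pyrastri,29,29,0
Insecta,Coleoptera,Coccinellidae,Hippodamia variegata,113,109,0
Insecta,Coleoptera,Coccinellidae,Coccinella undecimpunctata,30,28,0
Insecta,Coleoptera,Coccinellidae,Oenopia conglobata,23,23,0
Insecta,Neuroptera,Chrysopidae,Chrysoperla nipponensis,39,38,0
Insecta,Neuroptera,Chrysopidae,Chrysoperla carnea,62,62,0
Insecta,Hemiptera,Miridae,Deraeocoris punctulatus,101,100,0
Arachnida,Araneae,Philodromidae,Thanatus vulgaris,17,16,0
Arachnida,Araneae,Philodromidae,Philodromus alascensis,21,19,0
Arachnida,Araneae,Philodromidae,Philodromus cespitum,22,19,0
Arachnida,Araneae,Thomisidae,Ebrechtella tricuspidata,69,66,28
Arachnida,Araneae,Thomisidae,Xysticus ephippiatus,37,37,7
Arachnida,Araneae,Thomisidae,Spiracme striatipes,13,13,0
Arachnida,Araneae,Lycosidae,Lycosa ishikariana,15,15,0
Arachnida,Araneae,Lycosidae,Pardosa astrigera,14,14,0
Arachnida,Araneae,Linyphiidae,Hylyphantes graminicola,51,51,6
Arachnida,Araneae,Linyphiidae,Microlinyphia pusilla,34,32,0
Arachnida,Araneae,Theridiidae,Steatoda albomaculata,18,18,0
Arachnida,Araneae,Tetragnathidae,Tetragnatha extensa,29,29,0
Arachnida,Araneae,Oxyopidae,Oxyopes sertatus,11,11,4
Arachnida,Araneae,Araneidae,Neoscona adianta,28,28,0
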