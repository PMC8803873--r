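species_id,lineage,fb_type,taxon_order,size_min_mm,size_max_mm,lightness_pct,toughness
Fomes_fomentarius,Basidiomycota,pileate-sessile,Polyporales,100,450,46.5,
Trametes_versicolor,Basidiomycota,pileate-sessile,Polyporales,40,100,55.2,
Gloeophyllum_sepiarium,Basidiomycota,pileate-sessile,Gloeophyllales,30,120,32.8,
Mycena_galericulata,Basidiomycota,pileate-stipitate,Agaricales,20,60,62.0,
Pluteus_cervinus,Basidiomycota,pileate-stipitate,Agaricales,40,100,48.7,
Pholiota_squarrosa,Basidiomycota,pileate-stipitate,Agaricales,30,120,71.3,
Stereum_hirsutum,Basidiomycota,pileate-sessile,Russulales,10,40,60.1,tough
Xylaria_hypoxylon,Ascomycota,perithecia,,2,8,24.9,
Hypoxylon_fragiforme,Ascomycota,perithecia,,3,10,30.5,
Ascocoryne_sarcoides,Ascomycota,apothecia,,2,10,41.2,
Bisporella_citrina,Ascomycota,apothecia,,1,3,78.4,
Scutellinia_scutellata,Ascomycota,apothecia,,2,10,45.0,
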