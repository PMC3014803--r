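# filters: synthetic demonstration table (hand-written, not field data)
taxon_id,species,family,order,guild,count
t01,Pheidole_sp1,Formicidae,Hymenoptera,scavenger,4120
t02,Solenopsis_sp1,Formicidae,Hymenoptera,scavenger,980
t03,Blapstinus_sp1,Tenebrionidae,Coleoptera,scavenger,310
t04,Metius_sp1,Carabidae,Coleoptera,predator,205
t05,Trirammatus_sp1,Carabidae,Coleoptera,predator,118
t06,Mummucia_sp1,Mummuciidae,Solifugae,predator,64
t07,Lycosa_sp1,Lycosidae,Araneae,predator,151
t08,Steatoda_sp1,Theridiidae,Araneae,predator,43
t09,Sminthurus_sp1,Sminthuridae,Collembola,scavenger,92
t10,Dichroplus_sp1,Acrididae,Orthoptera,herbivore,87
t11,Dichroplus_sp2,Acrididae,Orthoptera,herbivore,26
t12,Phloeothrips_sp1,Phlaeothripidae,Thysanoptera,herbivore,55
t13,Nysius_sp1,Lygaeidae,Hemiptera,herbivore,18
t14,Geocoris_sp1,Geocoridae,Hemiptera,predator,9
t15,Armadillidium_sp1,Armadillidiidae,Isopoda,scavenger,5
t16,Juvenile_indet1,Lycosidae,Araneae,unknown,12
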