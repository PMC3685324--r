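id	species	family	clade
spA01_1	spA01	famA01	songbird
spA01_3	spA01	famA01	songbird
spA01_2	spA01	famA01	songbird
spA04_3	spA04	famA02	songbird
spA04_2	spA04	famA02	songbird
spA04_1	spA04	famA02	songbird
spA02_3	spA02	famA03	songbird
spA02_1	spA02	famA03	songbird
spA02_2	spA02	famA03	songbird
spA03_3	spA03	famA04	songbird
spA03_2	spA03	famA04	songbird
spA03_1	spA03	famA04	songbird
spB01_2	spB01	famB01	nonpasserine
spB01_1	spB01	famB01	nonpasserine
spB01_3	spB01	famB01	nonpasserine
spB02_1	spB02	famB02	nonpasserine
spB02_3	spB02	famB02	nonpasserine
spB02_2	spB02	famB02	nonpasserine
spB03_1	spB03	famB03	nonpasserine
spB03_2	spB03	famB03	nonpasserine
spB03_3	spB03	famB03	nonpasserine
spB04_1	spB04	famB04	nonpasserine
spB04_3	spB04	famB04	nonpasserine
spB04_2	spB04	famB04	nonpasserine
outgroup_1	outgroup	outgroup	outgroup
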