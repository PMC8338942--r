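bin_id,stages,t_old_ma,t_young_ma
Or5,Katian;Hirnantian,453.0,443.8
S1,Rhuddanian;Aeronian;Telychian,443.8,433.4
S2,Sheinwoodian;Homerian,433.4,427.4
S3,Gorstian;Ludfordian;Pridoli,427.4,419.2
D1,Lochkovian;Pragian,419.2,407.6
D2,Emsian,407.6,393.3
D3,Eifelian;Givetian,393.3,382.7
D4,Frasnian,382.7,372.2
D5,Famennian,372.2,358.9
C1,Tournaisian,358.9,346.7
C2,early Visean,346.7,338.8
C3,late Visean;Serpukhovian,338.8,323.2
C4,Bashkirian,323.2,315.2
C5,Moscovian;Kasimovian,315.2,303.7
C6,Gzhelian,303.7,298.9
P1,Asselian;Sakmarian,298.9,290.1
P2,Artinskian,290.1,283.5
P3,Kungurian;Roadian,283.5,268.8
P4,Wordian;Capitanian,268.8,259.8
P5,Wuchiapingian;Changhsingian,259.8,252.2
T1,Induan;Olenekian,252.2,247.2
T2,Anisian;Ladinian,247.2,237.0
T3,Carnian,237.0,227.0
T4,Norian,227.0,208.5
T5,Rhaetian,208.5,201.3
J1,Hettangian;Sinemurian,201.3,190.8
J2,Pliensbachian,190.8,182.7
J3,Toarcian;Aalenian,182.7,170.3
J4,Bajocian;Bathonian;Callovian,170.3,163.5
J5,Oxfordian,163.5,157.3
J6,Kimmeridgian;Tithonian,157.3,145.0
K1,Berriasian;Valanginian,145.0,133.9
K2,Hauterivian;Barremian,133.9,126.3
K3,Aptian,126.3,113.0
K4,Albian,113.0,100.5
K5,Cenomanian,100.5,93.9
K6,Turonian;Coniacian;Santonian,93.9,83.6
K7,Campanian,83.6,72.1
K8,Maastrichtian,72.1,66.0
Pg1,Danian;Selandian;Thanetian,66.0,56.0
Pg2,Ypresian,56.0,47.8
Pg3,Lutetian,47.8,41.2
Pg4,Bartonian;Priabonian,41.2,33.9
Pg5,Rupelian;Chattian,33.9,23.03
Ng1,Aquitanian;Burdigalian,23.03,15.97
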