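species_id,scientific_name,guild
C_nigra,Ciconia nigra,G1
A_alba,Ardea alba,G1
A_cinerea,Ardea cinerea,G1
C_boyciana,Ciconia boyciana,G1
A_cygnoides,Anser cygnoides,G1
G_leucogeranus,Grus leucogeranus,G2
G_monacha,Grus monacha,G2
C_columbianus,Cygnus columbianus,G2
G_grus,Grus grus,G3
A_albifrons,Anser albifrons,G3
A_fabalis,Anser fabalis,G3
P_leucorodia,Platalea leucorodia,G4
Larus_spp,Larus spp.,G5
P_onocrotalus,Pelecanus onocrotalus,G5
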