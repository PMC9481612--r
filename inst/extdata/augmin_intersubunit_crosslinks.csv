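# Intersubunit DSSO crosslinks identified in the purified human augmin
# (HAUS1-8) octamer with the HAUS6 C-terminus truncated, transcribed from
# the published table accompanying the deposited cryo-EM model (PDB 7SQK).
# Columns: id = published row label; peptideN_start = 1-based residue index
# of the peptide's first residue in its subunit; marked_posN = 1-based
# position of the crosslinked amino acid within the peptide; score = search
# engine total crosslink score; distance = published model C-alpha distance
# in Angstrom (empty when a peptide is absent from the model); flag: a =
# peptide 1 not present in structure, b = peptide 2 not present.
# Transcription notes: the crosslinked-residue marker of row 22's peptide 1
# (IKDDLTTIR) did not survive text extraction and is taken as position 2
# (the K), matching rows 18/30 which carry the same peptide. The published
# text cites rounded distances for rows 18/12/19 (54/59/312 A) that differ
# slightly from the table values carried here (51.8/57.4/314.3 A).
id,protein1,peptide1,peptide1_start,marked_pos1,protein2,peptide2,peptide2_start,marked_pos2,score,distance,flag
1,HAUS1,QKASEYESEAK,60,2,HAUS4,LHKTTWLR,73,3,13.2,9.6,
2,HAUS1,IEEAKRELDSIEAELTR,255,5,HAUS4,QATENKR,301,6,20.4,13.7,
3,HAUS2,NIPHLAANLKK,202,10,HAUS6,LTVDLHYLEKETK,330,10,43.3,16.8,
4,HAUS2,KMNQALAK,214,1,HAUS7,AVETVKK,335,6,28.4,10.6,
5,HAUS2,KQQNEVSSCIPK,241,1,HAUS7,MNELMEK,362,7,21.3,9.1,
6,HAUS3,CQLMASVTSHKSLR,122,11,HAUS4,ARLQQEVEEQLKKK,116,13,21.1,14.4,
7,HAUS4,ARLQQEVEEQLKKK,116,13,HAUS3,NKCQLMASVTSHK,121,2,32.4,17.9,
8,HAUS5,STLLKER,309,5,HAUS2,KQQNEVSSCIPK,241,1,21.3,19.4,
9,HAUS5,KLELEAAVTR,77,1,HAUS3,SGKPILEGAALDEALK,67,3,23.5,21.7,
10,HAUS5,KLELEAAVTR,77,1,HAUS3,TSDLKTPR,86,5,18.5,20.0,
11,HAUS5,AQFLQNLLLPQAKR,196,13,HAUS3,QELVLNQLIKQK,370,10,28.3,21.8,
12,HAUS5,KVVPTFEAVAPQSR,428,1,HAUS3,NTIDTKDYSTHR,339,6,20.4,57.4,
13,HAUS5,HRPGELKPLPTVLPSIHQLHPASPR,465,7,HAUS3,NTIDTKDYSTHR,339,6,37.3,,a
14,HAUS5,LRWVQAQGALQKLCS,619,12,HAUS3,IKAVSLED,596,2,20.3,10.5,
15,HAUS5,KLELEAAVTR,77,1,HAUS3,SGKPILEGAALDEALK,67,1,23.5,22.8,
16,HAUS5,STLLKER,309,5,HAUS7,MNELMEK,362,7,26.3,17.0,
17,HAUS6,HSVVEKQGEWHKK,367,6,HAUS2,KQQNEVSSCIPK,241,1,17.4,21.1,
18,HAUS6,IKDDLTTIR,358,2,HAUS3,LEKEVTQIK,323,3,18.3,51.8,
19,HAUS6,KMEPYDDHSNMEEKIQKVR,217,14,HAUS4,QVLNSYEVLGEEFDR,276,5,20.1,314.3,
20,HAUS6,LSDLKHMR,348,5,HAUS8,GKMSEGGR,60,2,15.7,,b
21,HAUS6,LSDLKHMR,348,5,HAUS8,DVTAKK,299,5,25.5,11.2,
22,HAUS6,IKDDLTTIR,358,2,HAUS8,DVTAKK,299,5,22.5,18.6,
23,HAUS7,QLQESAAKLHALR,231,8,HAUS2,NLEIELLKLEK,113,8,31.4,11.9,
24,HAUS7,QLQESAAKLHALR,231,8,HAUS2,LEKDTADVVHPFFLAQK,121,3,16.4,16.2,
25,HAUS7,QSDDWQWASASAKSEEEEKLAELAR,205,13,HAUS8,RAEKNLLIMCK,173,4,19.3,14.5,
26,HAUS7,SEEEEKLAELAR,219,6,HAUS8,NLLIMCKEK,177,7,32.4,15.7,
27,HAUS7,SEEEEKLAELAR,219,6,HAUS8,EKLQKK,185,5,18.4,18.1,
28,HAUS8,DVTAKK,299,5,HAUS6,FQKER,343,3,20.3,11.7,
29,HAUS8,ESGGAPKNTPLSEDDNPGASSAPAQATFISPSEDFSSSSQAEVPPSLSR,356,7,HAUS6,LSDLKHMR,348,5,31.4,,a
30,HAUS8,SFAQVLELSAEASKEAALANQEVWEETQGMAPPSR,311,14,HAUS6,IKDDLTTIR,358,2,18.5,16.5,
31,HAUS8,ESGGAPKNTPLSEDDNPGASSAPAQATFISPSEDFSSSSQAEVPPSLSR,356,7,HAUS6,YRIKDDLTTIR,355,4,25.3,,a
32,HAUS8,GKMSEGGR,60,2,HAUS7,FSSLKGVPTEVK,94,5,17.5,,a
33,HAUS8,SFAQVLELSAEASKEAALANQEVWEETQGMAPPSR,311,14,HAUS7,MNELMEK,362,7,26.5,20.1,
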