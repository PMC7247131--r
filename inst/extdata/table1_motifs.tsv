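# Transcription of the published summary table of 20 novel r-leader motifs.
# genes: retained regulated genes, transcription order, comma-separated.
# extended_genes: "often-extended" genes shown alongside the operon (plus-sign
#   annotation); can_extend marks rows whose operon can often be extended even
#   when the additional genes are not listed.
# rrna_similar: motif potentially similar to the ligand's rRNA binding site
#   (asterisk annotation).
# ligand_override: curated resolution where the printed gene symbol and
#   ligand column disagree as printed. The L20 row lists regulated gene rpsT
#   (conventionally encoding S20) yet assigns ligand L20 from a single-gene
#   operon; the override records the printed ligand without guessing the
#   intended symbol.
motif_id	ligand	basis	at_sign	genes	extended_genes	can_extend	lineage	domain	rating	rrna_similar	ligand_override
L2-Alphaproteobacteria	L2	Closest	FALSE	rplB,rpsS,rplV,rpsC	NA	FALSE	Alphaproteobacteria	Bacteria	?	FALSE	NA
L4-Archaeoglobi	L4	Prior	FALSE	rplC,rplD,rplW,rplB	NA	TRUE	Archaeoglobi	Archaea	?	FALSE	NA
L13-Bacteroidia	L13	Prior	FALSE	rplM,rpsI	rpsB	TRUE	Bacteroidia	Bacteria	Y	FALSE	NA
eL15-Euryarchaeota	eL15	Only	FALSE	rpl15e	NA	FALSE	Euryarchaeota	Archaea	Y	TRUE	NA
L17-ActinoProteobacteria	L17	Only	FALSE	rplQ	NA	FALSE	Actino- and Proteobacteria	Bacteria	Y	FALSE	NA
L20-Deltaproteobacteria	L20	Only	FALSE	rpsT	NA	FALSE	Deltaproteobacteria	Bacteria	Y	TRUE	L20
L31-Actinobacteria	L31	Only	FALSE	rpmE	NA	FALSE	Actinobacteria	Bacteria	Y	FALSE	NA
L31-Coriobacteria	L31	Only	FALSE	rpmE	NA	FALSE	Coriobacteria	Bacteria	Y	FALSE	NA
L31-Corynebacteriaceae	L31	Prior	TRUE	rpmE,rpmF	NA	FALSE	Corynebacteriaceae	Bacteria	Y	FALSE	NA
L31-Firmicutes	L31	Only	FALSE	rpmE	NA	FALSE	Firmicutes	Bacteria	Y	FALSE	NA
L31-Gammaproteobacteria	L31	Only	FALSE	rpmE	NA	FALSE	Gammaproteobacteria	Bacteria	Y	FALSE	NA
S4-Bacteroidia	S4	Prior	FALSE	rpsD,rpoA,rplQ	NA	FALSE	Bacteroidia	Bacteria	Y	FALSE	NA
S4-Clostridia	S4	Prior	FALSE	rpsM,rpsK,rpsD,rpoA,rplQ	NA	FALSE	Clostridia	Bacteria	Y	FALSE	NA
S4-Flavobacteria	S4	Prior	FALSE	rpsD,rpoA,rplQ	NA	FALSE	Flavobacteria	Bacteria	Y	FALSE	NA
S4-Fusobacteriales	S4	Prior	FALSE	rpsM,rpsK,rpsD,rpoA,rplQ	NA	FALSE	Fusobacteriales	Bacteria	Y	TRUE	NA
S6S18-Chlorobi	S6:S18	Prior	FALSE	rpsF,ssbA,rpsR,rplI	NA	FALSE	Chlorobi	Bacteria	Y	FALSE	NA
S15-Flavobacteria	S15	Only	FALSE	rpsO	NA	FALSE	Flavobacteria	Bacteria	?	FALSE	NA
S15-Halobacteria	S15	Prior	FALSE	rpsO,rps3ae	recJ	TRUE	Halobacteria	Archaea	Y	TRUE	NA
S15-Methanomicrobia	S15	Prior	FALSE	rpsO,rps3ae	recJ	TRUE	Methanomicrobia	Archaea	Y	TRUE	NA
S16-Flavobacteria	S16	Only	FALSE	rpsP,rimM	NA	FALSE	Flavobacteria	Bacteria	Y	FALSE	NA
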