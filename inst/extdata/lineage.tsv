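organism	superkingdom	phylum	species
escherichia coli	Bacteria	Pseudomonadota	Escherichia coli
escherichia coli k-12	Bacteria	Pseudomonadota	Escherichia coli
escherichia coli str. k-12 substr. mg1655	Bacteria	Pseudomonadota	Escherichia coli
pseudomonas aeruginosa	Bacteria	Pseudomonadota	Pseudomonas aeruginosa
pseudomonas aeruginosa pao1	Bacteria	Pseudomonadota	Pseudomonas aeruginosa
salmonella enterica	Bacteria	Pseudomonadota	Salmonella enterica
vibrio cholerae	Bacteria	Pseudomonadota	Vibrio cholerae
caulobacter vibrioides	Bacteria	Pseudomonadota	Caulobacter vibrioides
bacillus subtilis	Bacteria	Bacillota	Bacillus subtilis
bacillus subtilis subsp. subtilis str. 168	Bacteria	Bacillota	Bacillus subtilis
staphylococcus aureus	Bacteria	Bacillota	Staphylococcus aureus
listeria monocytogenes	Bacteria	Bacillota	Listeria monocytogenes
streptococcus pneumoniae	Bacteria	Bacillota	Streptococcus pneumoniae
mycobacterium tuberculosis	Bacteria	Actinomycetota	Mycobacterium tuberculosis
mycobacterium tuberculosis h37rv	Bacteria	Actinomycetota	Mycobacterium tuberculosis
streptomyces coelicolor	Bacteria	Actinomycetota	Streptomyces coelicolor
corynebacterium glutamicum	Bacteria	Actinomycetota	Corynebacterium glutamicum
synechocystis sp. pcc 6803	Bacteria	Cyanobacteriota	Synechocystis sp. PCC 6803
campylobacter jejuni	Bacteria	Campylobacterota	Campylobacter jejuni
helicobacter pylori	Bacteria	Campylobacterota	Helicobacter pylori
deinococcus radiodurans	Bacteria	Deinococcota	Deinococcus radiodurans
thermus thermophilus	Bacteria	Deinococcota	Thermus thermophilus
bacteroides thetaiotaomicron	Bacteria	Bacteroidota	Bacteroides thetaiotaomicron
sulfolobus acidocaldarius	Archaea	Thermoproteota	Sulfolobus acidocaldarius
methanocaldococcus jannaschii	Archaea	Methanobacteriota	Methanocaldococcus jannaschii
halobacterium salinarum	Archaea	Methanobacteriota	Halobacterium salinarum
saccharomyces cerevisiae	Eukaryota	Ascomycota	Saccharomyces cerevisiae
homo sapiens	Eukaryota	Chordata	Homo sapiens
escherichia virus t4	Viruses	Uroviricota	Escherichia virus T4
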