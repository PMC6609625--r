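gene_name	tissue_hits	pathway_flags	literature_support	notes
ABCC4			FALSE	
ACAT1	liver	ketone_metabolism	TRUE	acetoacetyl-CoA thiolase; ketone-body metabolism during lipomobilisation
ALDH3B1		other	FALSE	
ALOX12		other	FALSE	
ARL6IP5			FALSE	
ATP5F1		oxidative_phosphorylation	FALSE	respiratory-chain/mitochondrial subunit; no mechanistic literature link advanced
ATP5H		oxidative_phosphorylation	FALSE	respiratory-chain/mitochondrial subunit; no mechanistic literature link advanced
ATP5J		oxidative_phosphorylation	FALSE	respiratory-chain/mitochondrial subunit; no mechanistic literature link advanced
ATP5J2		oxidative_phosphorylation	FALSE	respiratory-chain/mitochondrial subunit; no mechanistic literature link advanced
BAT1			FALSE	
Bt.64131			FALSE	
C13H20ORF116			FALSE	
C1QBP		oxidative_phosphorylation	FALSE	respiratory-chain/mitochondrial subunit; no mechanistic literature link advanced
CAT		other	FALSE	
COPG			FALSE	
COX5A		oxidative_phosphorylation	FALSE	respiratory-chain/mitochondrial subunit; no mechanistic literature link advanced
COX5B		oxidative_phosphorylation	FALSE	respiratory-chain/mitochondrial subunit; no mechanistic literature link advanced
COX7A2		oxidative_phosphorylation	FALSE	respiratory-chain/mitochondrial subunit; no mechanistic literature link advanced
CUZD1			FALSE	
DDRGK1			FALSE	
DDX39B			FALSE	
EEF1B			FALSE	
GPAM		other	FALSE	
HIST1H4A			FALSE	
IG			FALSE	
IVD	liver;adipose	ketone_metabolism	TRUE	leucine degradation toward HMG-CoA, a ketogenesis intermediate
LF			FALSE	
LMAN1			FALSE	
LOC789567			FALSE	
LRPAP1			FALSE	
LRRC59	liver;adipose	cell_proliferation	TRUE	required for nuclear import of FGF1; mammary epithelial proliferation
Man8			FALSE	
MGC137099			FALSE	
MYCBP			FALSE	
NDUFA5		oxidative_phosphorylation	FALSE	respiratory-chain/mitochondrial subunit; no mechanistic literature link advanced
NDUFAB1		oxidative_phosphorylation	FALSE	respiratory-chain/mitochondrial subunit; no mechanistic literature link advanced
OSTC			FALSE	
PAFAH1B2			FALSE	
PCK2	liver;mammary	gluconeogenesis	TRUE	mitochondrial PEP carboxykinase; hepatic gluconeogenesis upregulated in early lactation
PLSCR2			FALSE	
RPL10A		other	FALSE	
RPL18		other	FALSE	
RPL6		other	FALSE	
RPL7		other	FALSE	
RPL7A		other	FALSE	
RPS13		other	FALSE	
SAA			FALSE	
SDHA	mammary	oxidative_phosphorylation	TRUE	complex II flavoprotein; TCA cycle and electron transport
SEC. 11C			FALSE	
SEC. 61A1			FALSE	
SLC15A2			FALSE	
SSR1			FALSE	
SURF4			FALSE	
SYPL1			FALSE	
TMED9			FALSE	
TMEM43			FALSE	
TREM1			FALSE	
TXNDC4			FALSE	
UQCRC1	mammary	oxidative_phosphorylation	TRUE	complex III core subunit; respiratory chain and NADPH-linked proton transfer
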