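gene,pathway
IDH1,metabolism
IDH2,metabolism
PTEN,metabolism
STK11,metabolism
TP53,p53
MDM2,p53
CDKN2A,p53
RB1,genome_integrity
UBR5,genome_integrity
EGFR,rtk_signaling
EPHA7,rtk_signaling
FLT3,rtk_signaling
BRAF,rtk_signaling
MET,rtk_signaling
MAP2K2,rtk_signaling
FGFR1,rtk_signaling
KIT,rtk_signaling
PDGFRA,rtk_signaling
NF1,rtk_signaling
PIK3CA,rtk_signaling
AKT2,rtk_signaling
PTCH1,hedgehog
ATRX,chromatin_remodeling
KMT2D,chromatin_remodeling
ARID1A,chromatin_remodeling
SETD2,chromatin_remodeling
TAF1,chromatin_remodeling
MN1,transcription
NOTCH1,notch
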