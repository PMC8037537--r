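# Default 3'UTR cis-regulatory element motif table (IUPAC, RNA alphabet).
# One row per element class scanned in mRNA 3'UTRs. Patterns are
# literature-standard consensus choices, simplified where the literature gives
# a structural rather than a sequence definition:
#   MBE      Musashi-binding element, (A/G)UAGU core (Imai et al. 2001).
#   GAIT     interferon-gamma-activated inhibitor of translation; bipartite
#            stem-loop. Reduced here to a U/C-rich loop core that must sit in
#            a hairpin with >= min_stem complementary flanking base pairs.
#   CPE      cytoplasmic polyadenylation element UUUUUAU with the common
#            degenerate variant UUUUAAU (W = A/U at position 5).
#   ARE      AU-rich destabilization element, AUUUA pentamer.
#   MOS-PRE  U-rich polyadenylation response element (Mos-type octamer).
#   GU-rich  GU-rich destabilization element, UGUUUGUUUGU-like repeat.
#   UNR      UNR/CSDE1 binding site, purine-rich AAG-containing consensus.
# Edit this file to change the scanned patterns; U/T equivalence is applied on
# load and all coordinates are 1-based closed intervals.
name	pattern	requires_hairpin	min_stem
MBE	RUAGU	FALSE	0
GAIT	AAUCCCU	TRUE	4
CPE	UUUUWAU	FALSE	0
ARE	AUUUA	FALSE	0
MOS-PRE	AUUUUAAU	FALSE	0
GU-rich	UGUUUGUUUGU	FALSE	0
UNR	AAGUAA	FALSE	0
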