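# Built-in CENP-B-related motifs used for bovine satellite analysis.
# cenpb_canonical : canonical 17-bp CENP-B box
# cenpb_consensus : CENP-B box consensus; the nine unambiguous positions
#                   are the core nucleotides required for DNA binding
# cenpb_element   : relaxed 7-bp CENP-B element
# bos_cenpb       : proposed conserved CENP-B-box-like motif in Bos
name	iupac
cenpb_canonical	YTTCGTTGGAARCGGGA
cenpb_consensus	NTTCGNNNNANNCGGGN
cenpb_element	AAACGGG
bos_cenpb	YTCCAGWYRARGCAGGR
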