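# Synthetic example model (invented for demonstration; not a curated network).
# A small goblet-cell-flavoured cascade: growth-factor signalling increases
# mucin transcription, a repressor limits it.
SET Species = "human"
SET Tissue = "airway epithelium"
act(p(HGNC:EGFR)) increases act(p(HGNC:MAPK1))
act(p(HGNC:MAPK1)) increases p(HGNC:SPDEF)
p(HGNC:SPDEF) increases bp(GO:"mucus secretion")
p(HGNC:FOXA2) decreases bp(GO:"mucus secretion")
act(p(HGNC:MAPK1)) decreases p(HGNC:FOXA2)
p(HGNC:SPDEF) increases r(HGNC:MUC5AC)
p(HGNC:SPDEF) increases r(HGNC:MUC5B)
p(HGNC:FOXA2) decreases r(HGNC:MUC5AC)
p(HGNC:FOXA2) increases r(HGNC:SCGB1A1)
act(p(HGNC:EGFR)) increases r(HGNC:AREG)
act(p(HGNC:MAPK1)) increases r(HGNC:DUSP1)
UNSET Tissue
UNSET Species
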