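# Excluded chemical components: common crystallisation additives, buffers,
# detergents, solutes and ubiquitous cofactors.  This list is an editable
# approximation; the small-compound rule (<= 5 heavy atoms) is separate.
comp_id	category
GOL	cryoprotectant
EDO	cryoprotectant
PEG	precipitant
PG4	precipitant
P6G	precipitant
MPD	precipitant
DMS	solvent
ACT	buffer
FMT	buffer
CIT	buffer
TLA	buffer
TRS	buffer
EPE	buffer
MES	buffer
BME	reductant
DTT	reductant
BOG	detergent
LDA	detergent
SDS	detergent
NAD	cofactor
NAI	cofactor
NAP	cofactor
NDP	cofactor
FAD	cofactor
FMN	cofactor
HEM	cofactor
HEC	cofactor
PLP	cofactor
COA	cofactor
ACO	cofactor
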