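class	headgroup_category	has_phosphorus	is_chloroplast	is_betaine	is_membrane	n_chains
PC	phospholipid	TRUE	FALSE	FALSE	TRUE	2
PG	phospholipid	TRUE	TRUE	FALSE	TRUE	2
PE	phospholipid	TRUE	FALSE	FALSE	TRUE	2
PI	phospholipid	TRUE	FALSE	FALSE	TRUE	2
PS	phospholipid	TRUE	FALSE	FALSE	TRUE	2
SQDG	glycolipid	FALSE	TRUE	FALSE	TRUE	2
MGDG	glycolipid	FALSE	TRUE	FALSE	TRUE	2
DGDG	glycolipid	FALSE	TRUE	FALSE	TRUE	2
GADG	glycolipid	FALSE	FALSE	FALSE	TRUE	2
DGTS/A	betaine	FALSE	FALSE	TRUE	TRUE	2
DGCC	betaine	FALSE	FALSE	TRUE	TRUE	2
TAG	neutral	FALSE	FALSE	FALSE	FALSE	3
DAG	neutral	FALSE	FALSE	FALSE	FALSE	2
other	other	FALSE	FALSE	FALSE	FALSE	2
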