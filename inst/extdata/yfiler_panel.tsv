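locus	repeat_unit	duplicated
DYS19	4	FALSE
DYS389I	4	FALSE
DYS389II	4	FALSE
DYS390	4	FALSE
DYS391	4	FALSE
DYS392	3	FALSE
DYS393	4	FALSE
DYS437	4	FALSE
DYS438	5	FALSE
DYS439	4	FALSE
DYS448	6	FALSE
DYS456	4	FALSE
DYS458	4	FALSE
DYS635	4	FALSE
YGATAH4	4	FALSE
DYS385	4	TRUE
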