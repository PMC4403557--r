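genome_id	biotin	cobalamin	folate	niacin	pantothenate	pyridoxine	riboflavin	thiamin
SYN001	0	0	1	0	0	1	0	1
SYN002	0	0	0	0	0	1	1	1
SYN003	0	0	1	0	0	0	1	0
SYN004	0	1	0	1	1	1	1	1
SYN005	1	0	1	1	0	1	0	0
SYN006	0	1	0	1	1	0	0	0
SYN007	0	0	0	1	1	1	1	0
SYN008	0	0	0	1	0	0	0	1
SYN009	0	0	0	0	1	1	1	1
SYN010	0	1	1	1	0	0	1	1
SYN011	1	1	1	0	1	0	1	1
SYN012	1	0	0	1	1	1	1	1
SYN013	0	0	1	0	1	1	1	0
SYN014	0	0	0	1	1	1	0	0
SYN015	0	0	1	1	1	0	1	0
SYN016	0	0	0	1	1	1	0	1
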