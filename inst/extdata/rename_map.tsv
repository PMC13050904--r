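# Gene-name harmonization map for the HsOr annotation update (HSAL70 ->
# current assembly names). Exactly the 21 printed entries: 19 renames plus
# one name swap recorded as 2 rows flagged swap=TRUE. Entries are applied
# simultaneously over the whole vocabulary (the list is chained:
# HsOr257.2 -> HsOr258 while old HsOr258 -> HsOr386).
old_name	new_name	swap
HsOr307.1	HsOr307	FALSE
HsOr307.2	HsOr380	FALSE
HsOr131.1	HsOr131	FALSE
HsOr131.2	HsOr381	FALSE
HsOr93.1	HsOr93	FALSE
HsOr93.2	HsOr382	FALSE
HsOr89.1	HsOr89	FALSE
HsOr89.2	HsOr383	FALSE
HsOr77.1	HsOr77	FALSE
HsOr77.2	HsOr384	FALSE
HsOr257.1	HsOr257	FALSE
HsOr257.2	HsOr258	FALSE
HsOr257.3	HsOr259	FALSE
HsOr257.4	HsOr385	FALSE
HsOr258	HsOr386	FALSE
HsOr182.1	HsOr182	FALSE
HsOr182.2	HsOr387	FALSE
HsOr211.1	HsOr211	FALSE
HsOr211.2	HsOr388	FALSE
LOC105187615	HsOr303	FALSE
HsOr378	HsOr379	TRUE
HsOr379	HsOr378	TRUE
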