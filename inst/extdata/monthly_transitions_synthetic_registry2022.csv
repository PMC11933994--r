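stratum,parameter,value
18-44,p_progress,0.0358107193317713
45-64,p_progress,0.0318515595015006
65-79,p_progress,0.0265264455124075
18-44,p_list_ckd,0.00875769286002159
45-64,p_list_ckd,0.00639111990021002
65-79,p_list_ckd,0.00385089223397528
18-44,p_list_dialysis,0.00858545754505979
45-64,p_list_dialysis,0.00547959116087149
65-79,p_list_dialysis,0.00294889796379894
18-44,p_ldt_unlisted,0.00127172004158294
45-64,p_ldt_unlisted,0.000820420625463392
65-79,p_ldt_unlisted,0.000411928646531168
18-44,p_ldt_listed,0
45-64,p_ldt_listed,0
65-79,p_ldt_listed,0
18-44,p_ddt_listed,0.024349796592971
45-64,p_ddt_listed,0.0207441979224688
65-79,p_ddt_listed,0.0164120259998142
18-44,p_removal,0.00254486421784939
45-64,p_removal,0.00521732104380446
65-79,p_removal,0.00980413782956979
18-44,p_death_ckd,0.00168691875069449
45-64,p_death_ckd,0.00425248995146366
65-79,p_death_ckd,0.0086085155480794
18-44,p_death_dialysis,0.00420648345011743
45-64,p_death_dialysis,0.0107921228397567
65-79,p_death_dialysis,0.0205263249071411
18-44,p_death_listed,0.00171594596558355
45-64,p_death_listed,0.00382634974381868
65-79,p_death_listed,0.00700317501961834
18-44,p_death_removed,0.00691516857453089
45-64,p_death_removed,0.0165006930610598
65-79,p_death_removed,0.0289485358314449
18-44,p_death_posttx,0.000833993715633308
45-64,p_death_posttx,0.00207952716196236
65-79,p_death_posttx,0.00418987976206076
18-44,p_graft_failure,0.00388380161260671
45-64,p_graft_failure,0.00340295747373254
65-79,p_graft_failure,0.00343825848328172
18-44,p_periop_death,0.003
45-64,p_periop_death,0.003
65-79,p_periop_death,0.003
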