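gene_id	protein	pathway	rpkm	sd
F7O84_RS17360	uronate isomerase	entner_doudoroff	5852	2398
F7O84_RS17370	tagaturonate reductase	entner_doudoroff	3067	1236
F7O84_RS17375	altronate dehydratase	entner_doudoroff	8426	3296
F7O84_RS17390	2-dehydro-3-deoxygluconokinase	entner_doudoroff	3863	1343
F7O84_RS17395	2-dehydro-3-deoxyphosphogluconate aldolase	entner_doudoroff	1752	245
F7O84_RS03200	pyruvate:ferredoxin oxidoreductase	acetate_production	4145	278
F7O84_RS03160	pyruvate formate lyase	acetate_production	1893	651
F7O84_RS05985	phosphate acetyltransferase	acetate_production	1500	176
F7O84_RS05980	acetate kinase	acetate_production	1625	200
F7O84_RS07405	formate dehydrogenase	wood_ljungdahl	14	3
F7O84_RS05385	formate-tetrahydrofolate ligase	wood_ljungdahl	256	58
F7O84_RS05380	methylene-THF dehydrogenase/cyclohydrolase	wood_ljungdahl	236	9
F7O84_RS08335	methyl-THF reductase	wood_ljungdahl	126	13
F7O84_RS02745	methyl-THF:corrinoid methyltransferase	wood_ljungdahl	144	19
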