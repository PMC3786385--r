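family	species	type	reference	lineage
Amaranthaceae	Alternanthera ficoides	C3-C4	bib58	eudicot
Amaranthaceae	Alternanthera tenella	C3-C4	bib17	eudicot
Amaranthaceae	Alternanthera pungens	C4	bib18	eudicot
Asteraceae	Flaveria cronquistii	C3		eudicot
Asteraceae	Flavera pringlei	C3		eudicot
Asteraceae	Flaveria robusta	C3		eudicot
Asteraceae	Flaveria angustifolia	C3-C4		eudicot
Asteraceae	Flaveria anomala	C3-C4	bib44	eudicot
Asteraceae	Flaveria chloraefolia	C3-C4	bib32	eudicot
Asteraceae	Flaveria floridana	C3-C4	bib2	eudicot
Asteraceae	Flaveria linearis	C3-C4	bib7	eudicot
Asteraceae	Flaveria oppositifolia	C3-C4	bib45	eudicot
Asteraceae	Flaveria ramosissima	C3-C4	bib64	eudicot
Asteraceae	Flaveria sonorensis	C3-C4	bib10	eudicot
Asteraceae	Flaveria brownie	C3-C4	bib51	eudicot
Asteraceae	Flaveria vaginata	C3-C4	bib50	eudicot
Asteraceae	Flaveria pubescens	C3-C4	bib23	eudicot
Asteraceae	Flaveria australasica	C4		eudicot
Asteraceae	Flaveria bidentis	C4		eudicot
Asteraceae	Flaveria kochiana	C4		eudicot
Asteraceae	Flaveria trinervia	C4		eudicot
Asteraceae	Parthenium incanum	C3	bib53	eudicot
Asteraceae	Parthenium hysterophorus	C3-C4	bib17	eudicot
Boraginaceae	Heliotropium europaeum	C3		eudicot
Boraginaceae	Heliotropium calcicola	C3	bib77	eudicot
Boraginaceae	Heliotropium convolvulaceum	C3-C4	bib54	eudicot
Boraginaceae	Heliotropium greggii	C3-C4		eudicot
Boraginaceae	Heliotropium polyphyllum	C4		eudicot
Brassicaceae	Moricandia foetida	C3	bib33	eudicot
Brassicaceae	Moricandia arvensis	C3-C4	bib61	eudicot
Brassicaceae	Moricandia spinosa	C3-C4	bib5	eudicot
Brassicaceae	Moricandia nitens	C3-C4	bib62	eudicot
Brassicaceae	Raphanus sativus	C3	bib74	eudicot
Brassicaceae	Diplotaxis muralis	C3-C4	bib75	eudicot
Brassicaceae	Diplotaxis tenuifolia	C3-C4		eudicot
Chenopodiaceae	Salsola oreophila	C3	bib56	eudicot
Chenopodiaceae	Salsola arbusculiformis	C3-C4	bib78	eudicot
Chenopodiaceae	Salsola arbuscula	C4		eudicot
Cleomaceae	Cleome spinosa	C3	bib79	eudicot
Cleomaceae	Cleome paradoxa	C3-C4	bib41	eudicot
Cleomaceae	Cleome gynandra	C4		eudicot
Cyperaceae	Eleocharis acuta	C3	bib8	monocot
Cyperaceae	Eleocharis acicularis	C3-C4	bib37	monocot
Cyperaceae	Eleocharis tetragona	C4		monocot
Euphorbiaceae	Euphorbia angusta	C3		eudicot
Euphorbiaceae	Euphorbia acuta	C3-C4	bib68	eudicot
Euphorbiaceae	Euphorbia lata	C3-C4		eudicot
Euphorbiaceae	Euphorbia mesembryanthemifolia	C4		eudicot
Molluginaceae	Mollugo tenella	C3		eudicot
Molluginaceae	Mollugo verticillata	C3-C4	bib70	eudicot
Molluginaceae	Mollugo naudicalis	C3-C4	bib38	eudicot
Molluginaceae	Mollugo pentaphylla	C3-C4	bib12	eudicot
Molluginaceae	Mollugo cerviana	C4		eudicot
Poaceae	Avena sativa	C3	bib71	monocot
Poaceae	Neurachne tenuifolia	C3	bib27	monocot
Poaceae	Neurachne minor	C3-C4	bib7	monocot
Poaceae	Neurachne munroi	C4		monocot
Poaceae	Panicum bisculatum	C3	bib22	monocot
Poaceae	Panicum hians	C3-C4	bib43	monocot
Poaceae	Panicum milioides	C3-C4	bib46	monocot
Poaceae	Panicum miliaceum	C4	bib60;bib59;bib31;bib26	monocot
Poaceae	Saccharum officinarum	C4	bib71	monocot
Poaceae	Sorghum bicolor	C4	bib71	monocot
Poaceae	Triticum aestivum	C3	bib71	monocot
Poaceae	Zea mays	C4	bib71	monocot
Portulaceae	Sesuvium portulacastrum	C3		eudicot
Portulaceae	Portulaca cryptopetala	C3-C4	bib80	eudicot
Portulaceae	Portulaca oleracea	C4		eudicot
Scrophularaceae	Anticharis kaokoensis	C3	bib39	eudicot
Scrophularaceae	Anticharis ebracteata	C3-C4		eudicot
Scrophularaceae	Anticharis imbricate	C3-C4		eudicot
Scrophularaceae	Anticharis namibensis	C3-C4		eudicot
Scrophularaceae	Anticharis glandulosa	C4		eudicot
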