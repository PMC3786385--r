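species	type	bs_enlargement	vein_spacing_decrease	gdc_bs_specificity	bs_chloroplast_number	bs_chloroplast_size	co2_compensation_point	pepc_activity	pepc_m_specificity	ppdk_activity	ppdk_m_specificity	decarboxylase_activity	decarboxylase_bs_specificity	mdh_activity	mdh_m_specificity	rubisco_activity_decrease	rubisco_bs_specificity
Alternanthera ficoides	C3-C4	2	1	2	1	1	1	2	1	1	1	2	2	2	1	2	2
Alternanthera tenella	C3-C4	1	2	2	2	1	1	2	0	2	0	2	2	2	2	2	2
Flaveria angustifolia	C3-C4	2	1	1	2	2	1	1	1	2	2	0	0	0	0	0	2
Flaveria anomala	C3-C4	2	2	1	1	1	1	2	1	2	1	1	1	1	0	0	0
Flaveria chloraefolia	C3-C4	2	2	1	1	2	1	2	1	1	1	1	1	2	2	0	0
Flaveria floridana	C3-C4	1	1	1	2	2	1	2	1	1	1	2	2	1	2	1	2
Flaveria linearis	C3-C4	1	2	2	1	2	2	1	2	1	2	2	0	2	0	0	2
Flaveria oppositifolia	C3-C4	2	2	2	2	1	1	1	2	1	2	2	1	1	0	0	0
Flaveria ramosissima	C3-C4	1	2	1	2	1	2	2	2	2	1	1	1	2	0	2	0
Flaveria sonorensis	C3-C4	2	2	1	1	1	1	1	0	2	0	0	2	0	0	2	0
Flaveria brownie	C3-C4	1	2	2	1	2	1	2	1	2	1	2	1	2	1	1	0
Flaveria vaginata	C3-C4	2	1	2	1	2	2	2	1	2	2	0	2	2	2	0	2
Flaveria pubescens	C3-C4	0	2	2	0	2	0	2	2	0	2	2	0	2	2	2	2
Parthenium hysterophorus	C3-C4	2	2	1	1	1	1	2	0	2	0	0	2	2	0	2	2
Heliotropium convolvulaceum	C3-C4	2	2	1	0	0	1	0	0	2	2	2	2	0	0	0	0
Heliotropium greggii	C3-C4	1	1	2	2	2	2	0	0	0	0	0	2	2	0	2	2
Moricandia arvensis	C3-C4	1	2	2	1	2	2	1	1	2	2	2	1	1	2	0	2
Moricandia spinosa	C3-C4	1	1	1	1	2	2	2	1	2	2	2	0	2	2	2	0
Moricandia nitens	C3-C4	1	2	2	1	2	2	0	0	2	2	2	0	0	0	0	0
Diplotaxis muralis	C3-C4	2	2	0	0	2	2	2	0	2	0	2	2	0	0	2	0
Diplotaxis tenuifolia	C3-C4	2	2	1	2	1	2	1	1	0	2	0	2	2	2	0	0
Salsola arbusculiformis	C3-C4	2	2	2	0	2	2	0	0	2	2	2	2	0	2	0	0
Cleome paradoxa	C3-C4	1	2	1	2	1	2	2	1	2	2	2	2	1	0	0	2
Eleocharis acicularis	C3-C4	1	1	1	1	0	1	0	0	2	2	2	0	2	2	2	2
Euphorbia acuta	C3-C4	2	2	2	2	1	1	1	2	2	1	1	2	1	2	2	2
Euphorbia lata	C3-C4	1	2	2	2	1	2	2	2	1	0	1	2	2	0	0	2
Mollugo verticillata	C3-C4	1	2	0	2	2	0	0	0	0	0	2	0	0	0	2	2
Mollugo naudicalis	C3-C4	2	1	1	1	1	2	2	0	2	2	0	2	2	2	2	2
Mollugo pentaphylla	C3-C4	1	2	1	2	0	0	0	0	0	0	0	2	2	2	2	0
Neurachne minor	C3-C4	1	1	1	2	2	1	2	2	2	0	0	2	2	2	0	0
Panicum hians	C3-C4	2	1	1	2	1	2	1	2	2	0	2	2	2	0	2	2
Panicum milioides	C3-C4	2	2	1	2	0	2	2	2	2	0	2	2	2	0	2	2
Portulaca cryptopetala	C3-C4	1	1	2	1	2	1	1	2	1	1	1	1	2	1	1	2
Anticharis ebracteata	C3-C4	1	1	2	1	1	2	2	1	2	2	2	1	2	2	2	2
Anticharis imbricate	C3-C4	1	2	2	0	0	0	0	0	0	2	0	2	2	0	2	0
Anticharis namibensis	C3-C4	1	1	1	1	2	2	2	1	2	2	1	0	0	2	0	0
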