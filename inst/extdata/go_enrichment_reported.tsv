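term	gene_count	overlap_pct	p_value
GO:0045893~positive regulation of transcription, DNA-templated	65	4.11913815	3.77E-04
GO:0032148~activation of protein kinase B activity	9	0.57034221	7.54E-04
GO:0048566~embryonic digestive tract development	7	0.44359949	0.00109859
GO:0008284~positive regulation of cell proliferation	58	3.67553866	0.00112482
GO:0042445~hormone metabolic process	6	0.38022814	0.00168902
GO:0007517~muscle organ development	17	1.07731305	0.00194273
GO:0007506~gonadal mesoderm development	5	0.31685678	0.00229907
GO:0045669~positive regulation of osteoblast differentiation	13	0.82382763	0.00276343
GO:0010595~positive regulation of endothelial cell migration	11	0.69708492	0.0032291
GO:0001501~skeletal system development	22	1.39416984	0.00334284
GO:0008584~male gonad development	17	1.07731305	0.00344918
GO:0007507~heart development	27	1.71102662	0.00348898
GO:0001837~epithelial to mesenchymal transition	9	0.57034221	0.00490232
GO:0007283~spermatogenesis	47	2.97845374	0.00501205
GO:0008285~negative regulation of cell proliferation	48	3.0418251	0.00519815
GO:0007420~brain development	27	1.71102662	0.00577131
GO:0010719~negative regulation of epithelial to mesenchymal transition	7	0.44359949	0.00672
GO:0007338~single fertilization	12	0.76045627	0.00710376
GO:0001525~angiogenesis	30	1.90114068	0.0075737
GO:0007417~central nervous system development	19	1.20405577	0.0078835
GO:0045786~negative regulation of cell cycle	9	0.57034221	0.00839841
GO:1900042~positive regulation of interleukin-2 secretion	4	0.25348542	0.00879714
GO:0001822~kidney development	15	0.95057034	0.00892399
GO:0045944~positive regulation of transcription from RNA polymerase II promoter	101	6.40050697	0.00935017
GO:0007399~nervous system development	36	2.28136882	0.0097276
GO:0007169~transmembrane receptor protein tyrosine kinase signaling pathway	16	1.0139417	0.01009885
GO:0007548~sex differentiation	7	0.44359949	0.01054713
GO:0007219~Notch signaling pathway	18	1.14068441	0.01109893
GO:0035115~embryonic forelimb morphogenesis	8	0.50697085	0.01254616
GO:0002040~sprouting angiogenesis	7	0.44359949	0.01294749
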