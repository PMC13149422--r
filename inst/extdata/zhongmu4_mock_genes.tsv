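gene_id	contig	start	end
Msa0003450	chr1_1	5968700	5973519
Msa0017430	chr1_1	28886750	28888312
Msa0024030	chr1_1	46120252	46124953
Msa0026910	chr1_1	51020065	51024894
Msa0026930	chr1_1	51046598	51055042
Msa0026940	chr1_1	51066698	51082662
Msa0047940	chr1_1	81136416	81138639
Msa0074550	chr1_2	49202329	49217071
Msa0158960	chr1_4	28926482	28931424
Msa0424870	chr3_2	75184493	75186197
Msa1220120	chr8_1	83134376	83149446
Msa1220150	chr8_1	83161877	83163657
Msa1220160	chr8_1	83170520	83177900
Msa1220170	chr8_1	83180768	83182453
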