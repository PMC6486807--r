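taxon_a	taxon_b	bp	iv
Isoetes_flaccida	Huperzia_serrata	8	6
Selaginella_lepidophylla	Huperzia_serrata	4	2
Selaginella_lepidophylla	Isoetes_flaccida	10	8
S_vardei	Huperzia_serrata	5	3
S_vardei	Isoetes_flaccida	10	9
S_vardei	Selaginella_lepidophylla	5	3
S_indica	Huperzia_serrata	5	3
S_indica	Isoetes_flaccida	10	10
S_indica	Selaginella_lepidophylla	5	3
S_indica	S_vardei	0	0
S_remotifolia	Huperzia_serrata	5	3
S_remotifolia	Isoetes_flaccida	10	11
S_remotifolia	Selaginella_lepidophylla	5	3
S_remotifolia	S_vardei	3	3
S_remotifolia	S_indica	3	3
S_kraussiana	Huperzia_serrata	5	3
S_kraussiana	Isoetes_flaccida	10	12
S_kraussiana	Selaginella_lepidophylla	5	3
S_kraussiana	S_vardei	3	3
S_kraussiana	S_indica	3	3
S_kraussiana	S_remotifolia	0	0
S_lyallii	Huperzia_serrata	5	3
S_lyallii	Isoetes_flaccida	10	13
S_lyallii	Selaginella_lepidophylla	5	3
S_lyallii	S_vardei	3	3
S_lyallii	S_indica	3	3
S_lyallii	S_remotifolia	0	0
S_lyallii	S_kraussiana	0	0
S_sanguinolenta	Huperzia_serrata	5	3
S_sanguinolenta	Isoetes_flaccida	10	14
S_sanguinolenta	Selaginella_lepidophylla	5	3
S_sanguinolenta	S_vardei	3	3
S_sanguinolenta	S_indica	3	3
S_sanguinolenta	S_remotifolia	0	0
S_sanguinolenta	S_kraussiana	0	0
S_sanguinolenta	S_lyallii	0	0
S_tamariscina	Huperzia_serrata	4	2
S_tamariscina	Isoetes_flaccida	11	8
S_tamariscina	Selaginella_lepidophylla	4	2
S_tamariscina	S_vardei	5	4
S_tamariscina	S_indica	5	4
S_tamariscina	S_remotifolia	5	4
S_tamariscina	S_kraussiana	5	4
S_tamariscina	S_lyallii	5	4
S_tamariscina	S_sanguinolenta	5	4
S_doederleinii	Huperzia_serrata	4	2
S_doederleinii	Isoetes_flaccida	11	8
S_doederleinii	Selaginella_lepidophylla	4	2
S_doederleinii	S_vardei	5	4
S_doederleinii	S_indica	5	4
S_doederleinii	S_remotifolia	5	4
S_doederleinii	S_kraussiana	5	4
S_doederleinii	S_lyallii	5	4
S_doederleinii	S_sanguinolenta	5	4
S_doederleinii	S_tamariscina	0	0
S_moellendorffii	Huperzia_serrata	4	2
S_moellendorffii	Isoetes_flaccida	11	8
S_moellendorffii	Selaginella_lepidophylla	4	2
S_moellendorffii	S_vardei	5	4
S_moellendorffii	S_indica	5	4
S_moellendorffii	S_remotifolia	5	4
S_moellendorffii	S_kraussiana	5	4
S_moellendorffii	S_lyallii	5	4
S_moellendorffii	S_sanguinolenta	5	4
S_moellendorffii	S_tamariscina	0	0
S_moellendorffii	S_doederleinii	0	0
S_pennata	Huperzia_serrata	6	5
S_pennata	Isoetes_flaccida	13	11
S_pennata	Selaginella_lepidophylla	7	5
S_pennata	S_vardei	7	6
S_pennata	S_indica	7	6
S_pennata	S_remotifolia	7	6
S_pennata	S_kraussiana	7	6
S_pennata	S_lyallii	7	6
S_pennata	S_sanguinolenta	7	6
S_pennata	S_tamariscina	7	5
S_pennata	S_doederleinii	7	5
S_pennata	S_moellendorffii	7	5
S_bisulcata	Huperzia_serrata	6	5
S_bisulcata	Isoetes_flaccida	13	11
S_bisulcata	Selaginella_lepidophylla	7	5
S_bisulcata	S_vardei	7	6
S_bisulcata	S_indica	7	6
S_bisulcata	S_remotifolia	7	6
S_bisulcata	S_kraussiana	7	6
S_bisulcata	S_lyallii	7	6
S_bisulcata	S_sanguinolenta	7	6
S_bisulcata	S_tamariscina	7	5
S_bisulcata	S_doederleinii	7	5
S_bisulcata	S_moellendorffii	7	5
S_bisulcata	S_pennata	0	0
S_hainanensis	Huperzia_serrata	6	5
S_hainanensis	Isoetes_flaccida	12	10
S_hainanensis	Selaginella_lepidophylla	6	5
S_hainanensis	S_vardei	7	6
S_hainanensis	S_indica	7	6
S_hainanensis	S_remotifolia	7	6
S_hainanensis	S_kraussiana	7	6
S_hainanensis	S_lyallii	7	6
S_hainanensis	S_sanguinolenta	7	6
S_hainanensis	S_tamariscina	7	5
S_hainanensis	S_doederleinii	7	5
S_hainanensis	S_moellendorffii	7	5
S_hainanensis	S_pennata	3	2
S_hainanensis	S_bisulcata	3	2
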