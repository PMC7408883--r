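# mtrnr1_kb schema_version=1
# MT-RNR1 variants associated with aminoglycoside-induced ototoxicity.
# tier: strong = well-supported pharmacogenetic association;
#       needs_further_study = reported association awaiting validation.
position	ref	alt	tier	note	pmid_refs
1555	A	G	strong	principal ototoxicity variant m.1555A>G	.
1494	C	T	strong	well-supported ototoxicity variant m.1494C>T	.
669	T	C	needs_further_study	.	.
827	A	G	needs_further_study	.	.
896	A	G	needs_further_study	.	.
930	G	A	needs_further_study	.	.
961	T	C	needs_further_study	homopolymer context: m.961T flanked by C runs; indel calls unreliable	.
961	T	G	needs_further_study	homopolymer context: m.961T flanked by C runs; indel calls unreliable	.
988	G	A	needs_further_study	.	.
1005	T	C	needs_further_study	.	.
1048	C	T	needs_further_study	.	.
1189	T	C	needs_further_study	.	.
1243	T	C	needs_further_study	.	.
1438	G	A	needs_further_study	.	.
1462	G	A	needs_further_study	.	.
1537	C	T	needs_further_study	.	.
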