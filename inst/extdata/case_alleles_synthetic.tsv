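variant_id	case_alleles	in_databases
c.407T>C	223	TRUE
c.194A>T	80	TRUE
c.400+2dup	65	TRUE
c.294G>A	26	FALSE
c.188G>A	12	FALSE
c.521_523del	9	TRUE
c.81-3C>G	6	FALSE
c.1A>C	3	TRUE
c.329T>C	2	TRUE
c.58C>T	2	FALSE
c.23dup	1	FALSE
c.522_524del	1	FALSE
c.264G>T	1	FALSE
c.227C>T	1	FALSE
c.521_524del	1	FALSE
c.541T>C	1	TRUE
c.250G>A	1	TRUE
synthetic_v18	14	TRUE
synthetic_v19	14	TRUE
synthetic_v20	13	TRUE
synthetic_v21	13	TRUE
synthetic_v22	13	TRUE
synthetic_v23	5	TRUE
synthetic_v24	5	TRUE
synthetic_v25	5	TRUE
synthetic_v26	5	TRUE
synthetic_v27	5	TRUE
synthetic_v28	5	TRUE
synthetic_v29	2	TRUE
synthetic_v30	2	TRUE
synthetic_v31	2	TRUE
synthetic_v32	2	TRUE
synthetic_v33	2	TRUE
synthetic_v34	2	TRUE
synthetic_v35	2	TRUE
synthetic_v36	2	TRUE
synthetic_v37	2	TRUE
synthetic_v38	2	TRUE
synthetic_v39	1	FALSE
synthetic_v40	1	FALSE
synthetic_v41	1	FALSE
synthetic_v42	1	FALSE
synthetic_v43	1	FALSE
synthetic_v44	1	FALSE
synthetic_v45	1	FALSE
synthetic_v46	1	FALSE
synthetic_v47	1	FALSE
synthetic_v48	1	FALSE
synthetic_v49	1	FALSE
synthetic_v50	1	FALSE
synthetic_v51	1	FALSE
synthetic_v52	1	FALSE
synthetic_v53	1	FALSE
synthetic_v54	1	FALSE
synthetic_v55	1	FALSE
synthetic_v56	1	FALSE
synthetic_v57	1	FALSE
synthetic_v58	1	FALSE
synthetic_v59	1	FALSE
synthetic_v60	1	FALSE
synthetic_v61	1	FALSE
synthetic_v62	1	FALSE
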