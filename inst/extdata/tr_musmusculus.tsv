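symbol	alleles	synonyms
TRAV1	01=F|02=F
TRAV2	01=F|02=F
TRAV3-1	01=F|02=F
TRAV3-3	01=F
TRAV3-4	01=F
TRAV3D-3	01=F|02=F
TRAV3N-3	01=F
TRAV4-2	01=F
TRAV4-3	01=F
TRAV4-4/DV10	01=F|02=F
TRAV4D-3	01=F|02=F
TRAV4D-4	01=F|02=F
TRAV4N-3	01=F
TRAV4N-4	01=F
TRAV5-1	01=F
TRAV5-2	01=F
TRAV5-4	01=F|02=F
TRAV5D-4	01=F
TRAV5N-4	01=F
TRAV6-1	01=F
TRAV6-2	01=F
TRAV6-3	01=F|02=F
TRAV6-4	01=F
TRAV6-5	01=F|02=F
TRAV6-6	01=F|02=F
TRAV6-7/DV9	01=F|02=F
TRAV6D-3	01=F
TRAV6D-4	01=F
TRAV6D-5	01=F
TRAV6D-6	01=F|02=F
TRAV6D-7	01=F|02=F
TRAV6N-5	01=F
TRAV6N-6	01=F
TRAV6N-7	01=F
TRAV7-1	01=F
TRAV7-2	01=F
TRAV7-3	01=F|02=F
TRAV7-4	01=F|02=F
TRAV7-5	01=F
TRAV7-6	01=F|02=F
TRAV7D-2	01=F|02=F
TRAV7D-3	01=F
TRAV7D-4	01=F
TRAV7D-5	01=F
TRAV7D-6	01=F
TRAV7N-4	01=F
TRAV7N-5	01=F
TRAV7N-6	01=F
TRAV8-1	01=F
TRAV8-2	01=F
TRAV8D-1	01=F|02=F
TRAV8D-2	01=F|02=F
TRAV8N-2	01=F
TRAV9-1	01=F
TRAV9-2	01=F
TRAV9-3	01=F
TRAV9-4	01=F
TRAV9D-1	01=F
TRAV9D-2	01=F
TRAV9D-3	01=F
TRAV9D-4	01=F|02=F
TRAV9N-2	01=F
TRAV9N-3	01=F
TRAV9N-4	01=F
TRAV10	01=F|02=F
TRAV10D	01=F
TRAV10N	01=F
TRAV11	01=F
TRAV11D	01=F
TRAV11N	01=F
TRAV12-1	01=F
TRAV12-2	01=F
TRAV12-3	01=F
TRAV12D-1	01=F
TRAV12D-2	01=F|02=F
TRAV12D-3	01=F
TRAV12N-1	01=F
TRAV12N-2	01=F
TRAV12N-3	01=F
TRAV13-1	01=F
TRAV13-2	01=F
TRAV13-3	01=F
TRAV13-4/DV7	01=F|02=F
TRAV13-5	01=F
TRAV13D-1	01=F
TRAV13D-2	01=F
TRAV13D-3	01=F
TRAV13D-4	01=F
TRAV13N-1	01=F
TRAV13N-2	01=F
TRAV13N-3	01=F
TRAV13N-4	01=F
TRAV14-1	01=F|02=F
TRAV14-2	01=F
TRAV14-3	01=F
TRAV14D-1	01=F
TRAV14D-2	01=F
TRAV14D-3/DV8	01=F|02=F
TRAV14N-1	01=F
TRAV14N-2	01=F
TRAV14N-3	01=F
TRAV15-1/DV6-1	01=F|02=F
TRAV15-2/DV6-2	01=F
TRAV15D-1/DV6D-1	01=F|02=F
TRAV15D-2/DV6D-2	01=F
TRAV15N-1	01=F
TRAV15N-2	01=F
TRAV16	01=F
TRAV16D/DV11	01=F|02=F
TRAV16N	01=F
TRAV17	01=F
TRAV18	01=P
TRAV19	01=F
TRAV20	01=F
TRAV21/DV12	01=F|02=F
TRAJ2	01=F
TRAJ3	01=P
TRAJ4	01=P
TRAJ5	01=F
TRAJ6	01=F
TRAJ7	01=P
TRAJ9	01=F
TRAJ11	01=F
TRAJ12	01=F
TRAJ13	01=F
TRAJ15	01=F
TRAJ16	01=F
TRAJ17	01=F
TRAJ18	01=F
TRAJ19	01=P
TRAJ20	01=P
TRAJ21	01=F
TRAJ22	01=F
TRAJ23	01=F
TRAJ24	01=F
TRAJ25	01=P
TRAJ26	01=F
TRAJ27	01=F
TRAJ28	01=F
TRAJ29	01=P
TRAJ30	01=F
TRAJ31	01=F
TRAJ32	01=F
TRAJ33	01=F
TRAJ34	01=F
TRAJ35	01=F
TRAJ36	01=F
TRAJ37	01=F
TRAJ38	01=F
TRAJ39	01=F
TRAJ40	01=F
TRAJ41	01=P
TRAJ42	01=F
TRAJ43	01=F
TRAJ44	01=P
TRAJ45	01=F
TRAJ46	01=P
TRAJ47	01=ORF
TRAJ48	01=F
TRAJ49	01=F
TRAJ50	01=F
TRAJ52	01=F
TRAJ53	01=F
TRAJ54	01=P
TRAJ56	01=F
TRAJ57	01=F
TRAJ58	01=F
TRAJ59	01=P
TRAJ60	01=P
TRAJ61	01=P
TRBV1	01=F|02=F
TRBV2	01=F|02=F	TCRBV22S1A2N1T|TCRBV22S1
TRBV3	01=F
TRBV4	01=F|02=F
TRBV5	01=F|02=F
TRBV6	01=P
TRBV7	01=P
TRBV8	01=P
TRBV9	01=P
TRBV10	01=P
TRBV11	01=P
TRBV12-1	01=F
TRBV12-2	01=F|02=F
TRBV13-1	01=F|02=F
TRBV13-2	01=F|02=F
TRBV13-3	01=F
TRBV14	01=F
TRBV15	01=F|02=F
TRBV16	01=F
TRBV17	01=F
TRBV18	01=P
TRBV19	01=F|02=F
TRBV20	01=F|02=F
TRBV21	01=P
TRBV23	01=F
TRBV24	01=F
TRBV25	01=P
TRBV26	01=F|02=F
TRBV29	01=F|02=F
TRBV30	01=F
TRBV31	01=F|02=F
TRBD1	01=F
TRBD2	01=F
TRBJ1-1	01=F
TRBJ1-2	01=F
TRBJ1-3	01=F
TRBJ1-4	01=F
TRBJ1-5	01=F|02=F
TRBJ1-6	01=P
TRBJ1-7	01=F
TRBJ2-1	01=F
TRBJ2-2	01=F
TRBJ2-3	01=F
TRBJ2-4	01=F
TRBJ2-5	01=F
TRBJ2-6	01=P
TRBJ2-7	01=F
TRGV1	01=F|02=F
TRGV2	01=F|02=F
TRGV3	01=F
TRGV4	01=F
TRGV5	01=F
TRGV6	01=F|02=F
TRGV7	01=F
TRGJ1	01=F
TRGJ2	01=P
TRGJ3	01=F
TRGJ4	01=F
TRDV1	01=F
TRDV2-1	01=F
TRDV2-2	01=F|02=F
TRDV4	01=F
TRDV5	01=F
TRDD1	01=F
TRDD2	01=F
TRDJ1	01=F
TRDJ2	01=F
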