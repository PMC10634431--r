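symbol	alleles	synonyms
TRAV1-1	01=F
TRAV1-2	01=F|02=F
TRAV2	01=F
TRAV3	01=F
TRAV4	01=F
TRAV5	01=F
TRAV6	01=F
TRAV7	01=F
TRAV8-1	01=F
TRAV8-2	01=F|02=F
TRAV8-3	01=F
TRAV8-4	01=F|02=F
TRAV8-5	01=P
TRAV8-6	01=F|02=F
TRAV8-7	01=ORF
TRAV9-1	01=F
TRAV9-2	01=F|02=F
TRAV10	01=F
TRAV11	01=P
TRAV12-1	01=F
TRAV12-2	01=F|02=F
TRAV12-3	01=F
TRAV13-1	01=F|02=F
TRAV13-2	01=F
TRAV14/DV4	01=F|02=F|03=F
TRAV15	01=P
TRAV16	01=F
TRAV17	01=F
TRAV18	01=F
TRAV19	01=F
TRAV20	01=F|02=F
TRAV21	01=F|02=F
TRAV22	01=F
TRAV23/DV6	01=F|02=F
TRAV24	01=F
TRAV25	01=F
TRAV26-1	01=F|02=F
TRAV26-2	01=F
TRAV27	01=F
TRAV28	01=P
TRAV29/DV5	01=F|02=F
TRAV30	01=F|02=F
TRAV31	01=P
TRAV32	01=P
TRAV33	01=P
TRAV34	01=F
TRAV35	01=F|02=F
TRAV36/DV7	01=F|02=F
TRAV37	01=P
TRAV38-1	01=F|02=F
TRAV38-2/DV8	01=F
TRAV39	01=F
TRAV40	01=F
TRAV41	01=F
TRAJ1	01=ORF
TRAJ2	01=ORF
TRAJ3	01=F
TRAJ4	01=F
TRAJ5	01=F
TRAJ6	01=F
TRAJ7	01=F
TRAJ8	01=F
TRAJ9	01=F
TRAJ10	01=F
TRAJ11	01=F
TRAJ12	01=F
TRAJ13	01=F|02=F
TRAJ14	01=F
TRAJ15	01=F|02=F
TRAJ16	01=F
TRAJ17	01=F
TRAJ18	01=F
TRAJ19	01=ORF
TRAJ20	01=F
TRAJ21	01=F
TRAJ22	01=F
TRAJ23	01=F
TRAJ24	01=F|02=F
TRAJ25	01=ORF
TRAJ26	01=F
TRAJ27	01=F
TRAJ28	01=F
TRAJ29	01=F
TRAJ30	01=F
TRAJ31	01=F
TRAJ32	01=F|02=F
TRAJ33	01=F
TRAJ34	01=F
TRAJ35	01=F
TRAJ36	01=F
TRAJ37	01=F|02=F
TRAJ38	01=F
TRAJ39	01=F
TRAJ40	01=F
TRAJ41	01=F
TRAJ42	01=F
TRAJ43	01=F
TRAJ44	01=F
TRAJ45	01=F
TRAJ46	01=F
TRAJ47	01=F|02=F
TRAJ48	01=F
TRAJ49	01=F
TRAJ50	01=F
TRAJ51	01=P
TRAJ52	01=F
TRAJ53	01=F
TRAJ54	01=F
TRAJ55	01=P
TRAJ56	01=F
TRAJ57	01=F
TRAJ58	01=ORF
TRAJ59	01=P
TRAJ60	01=P
TRAJ61	01=P
TRBV1	01=P
TRBV2	01=F|02=F|03=F
TRBV3-1	01=F|02=F
TRBV3-2	01=P
TRBV4-1	01=F|02=F
TRBV4-2	01=F|02=F
TRBV4-3	01=F
TRBV5-1	01=F|02=F
TRBV5-2	01=P
TRBV5-3	01=ORF
TRBV5-4	01=F|02=F
TRBV5-5	01=F|02=F
TRBV5-6	01=F
TRBV5-7	01=P
TRBV5-8	01=F|02=F
TRBV6-1	01=F
TRBV6-2	01=F
TRBV6-3	01=F
TRBV6-4	01=F|02=F
TRBV6-5	01=F
TRBV6-6	01=F|02=F
TRBV6-7	01=P
TRBV6-8	01=F
TRBV6-9	01=F
TRBV7-1	01=P
TRBV7-2	01=F|02=F|03=F
TRBV7-3	01=F|02=F
TRBV7-4	01=F
TRBV7-5	01=P
TRBV7-6	01=F|02=F
TRBV7-7	01=F|02=F
TRBV7-8	01=F|02=F
TRBV7-9	01=F|02=F|03=F
TRBV8-1	01=P
TRBV8-2	01=P
TRBV9	01=F|02=F
TRBV10-1	01=F|02=F
TRBV10-2	01=F|02=F
TRBV10-3	01=F|02=F
TRBV11-1	01=F
TRBV11-2	01=F|02=F|03=F
TRBV11-3	01=F|02=F
TRBV12-1	01=P
TRBV12-2	01=P
TRBV12-3	01=F
TRBV12-4	01=F|02=F
TRBV12-5	01=F
TRBV13	01=F|02=F
TRBV14	01=F|02=F
TRBV15	01=F|02=F
TRBV16	01=F|02=F
TRBV17	01=ORF|02=ORF
TRBV18	01=F
TRBV19	01=F|02=F|03=F
TRBV20-1	01=F|02=F
TRBV21-1	01=P
TRBV22-1	01=P
TRBV23-1	01=ORF
TRBV24-1	01=F|02=F
TRBV25-1	01=F
TRBV26	01=P
TRBV27	01=F
TRBV28	01=F
TRBV29-1	01=F|02=F|03=F
TRBV30	01=F|02=F
TRBD1	01=F
TRBD2	01=F|02=F
TRBJ1-1	01=F
TRBJ1-2	01=F
TRBJ1-3	01=F
TRBJ1-4	01=F
TRBJ1-5	01=F
TRBJ1-6	01=F|02=F
TRBJ2-1	01=F
TRBJ2-2	01=F
TRBJ2-2P	01=ORF
TRBJ2-3	01=F
TRBJ2-4	01=F
TRBJ2-5	01=F
TRBJ2-6	01=F
TRBJ2-7	01=F|02=F
TRGV1	01=P
TRGV2	01=F|02=F
TRGV3	01=F|02=F
TRGV4	01=F|02=F
TRGV5	01=F|02=F
TRGV5P	01=P
TRGV6	01=P
TRGV7	01=P
TRGV8	01=F
TRGV9	01=F|02=F
TRGV10	01=ORF|02=ORF
TRGV11	01=ORF|02=ORF
TRGVA	01=P
TRGVB	01=P
TRGJ1	01=F|02=F
TRGJ2	01=F
TRGJP	01=F
TRGJP1	01=F
TRGJP2	01=F
TRDV1	01=F
TRDV2	01=F|02=F|03=F
TRDV3	01=F
TRDD1	01=F
TRDD2	01=F
TRDD3	01=F
TRDJ1	01=F
TRDJ2	01=F
TRDJ3	01=F
TRDJ4	01=ORF
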