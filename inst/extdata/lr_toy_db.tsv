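interaction_id	ligand	receptor
ix001	Pecam1	Cd177
ix002	Cd74	Mif
ix003	Il1b	Adrb2
ix004	Ccl4	Ccr5
ix005	Cxcl2	Dpp4
ix006	Cd28	Cd86
ix007	Ccl2	Ccr2
ix008	Ccl5	Ccr1
ix009	Cxcl12	Cxcr4
ix010	Cxcl1	Cxcr2
ix011	Il6	Il6ra
ix012	Il1a	Il1r1
ix013	Il10	Il10ra
ix014	Tnf	Tnfrsf1a
ix015	Tnf	Tnfrsf1b
ix016	Ifng	Ifngr1
ix017	Tgfb1	Tgfbr1
ix018	Il4	Il4ra
ix019	Il18	Il18r1
ix020	Csf1	Csf1r
ix021	Csf2	Csf2ra
ix022	Csf3	Csf3r
ix023	Kitl	Kit
ix024	Flt3l	Flt3
ix025	Cd40lg	Cd40
ix026	Icam1	Itgal
ix027	Vcam1	Itga4
ix028	Sele	Glg1
ix029	Selp	Selplg
ix030	Cx3cl1	Cx3cr1
ix031	Ccl3	Ccr5
ix032	Ccl19	Ccr7
ix033	Ccl21a	Ccr7
ix034	Cxcl13	Cxcr5
ix035	Cxcl9	Cxcr3
ix036	Cxcl10	Cxcr3
ix037	Il7	Il7r
ix038	Il15	Il15ra
ix039	Il2	Il2rb
ix040	Tslp	Crlf2
ix041	Apoe	Lrp1
ix042	App	Cd74
ix043	Mdk	Ncl
ix044	Ptn	Ptprz1
ix045	Vegfa	Flt1
ix046	Pgf	Flt1
ix047	Angpt1	Tek
ix048	Dll1	Notch1
ix049	Jag1	Notch2
ix050	Lgals9	Havcr2
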