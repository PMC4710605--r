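id,name,smiles,assay_outcome,ac50_uM,exposure_category,metabolism_code,parent_id,absorption_annotation,distribution_annotation,promiscuity_override,priority_printed,registry
chlorpyrifos_oxon,Chlorpyrifos oxon,CCOP(=O)(OCC)Oc1nc(Cl)c(Cl)cc1Cl,active,0.149,1,+,chlorpyrifos,Yes,Yes,,High,CAS:5598-15-2
pharmagsid_47259,PharmaGSID_47259,,active,0.287,4,-,,NA,NA,,Low,
carbofuran,Carbofuran,CNC(=O)Oc1cccc2CC(C)(C)Oc12,active,0.416,3,+-,carbosulfan,Yes,Yes,,High,CAS:1563-66-2
anthralin,Anthralin,Oc1cccc2c1C(=O)c1c(O)cccc1C2,active,0.512,2,-,,Yes,No,,Low,CAS:1143-38-0
naled,Naled,COP(=O)(OC)OC(Br)C(Cl)(Cl)Br,active,1.01,1,-,,Yes,Yes,,High,CAS:300-76-5
carbosulfan,Carbosulfan,CCCCN(CCCC)SN(C)C(=O)Oc1cccc2CC(C)(C)Oc12,active,1.21,1,+-,,Limited,Yes,,High,CAS:55285-14-8
raloxifene_hydrochloride,Raloxifene hydrochloride,Oc1ccc2c(c1)sc(-c1ccc(O)cc1)c2C(=O)c1ccc(OCCN2CCCCC2)cc1.Cl,active,1.85,2,-,,Limited,No,,Low,CAS:82640-04-8
benzylquinolinium_chloride,1-Benzylquinolinium chloride,[Cl-].C(c1ccccc1)[n+]1cccc2ccccc21,active,2.48,2,U,,Yes,Yes,TRUE,High,CAS:15619-48-4
besonprodil,Besonprodil,O=C1Nc2ccc(S(=O)CCN3CCC(Cc4ccc(F)cc4)CC3)cc2O1,active,3.49,3,-,,Yes,Yes,,High,
bendiocarb,Bendiocarb,CNC(=O)Oc1cccc2OC(C)(C)Oc12,active,4.09,3,-,,Yes,Yes,,High,CAS:22781-23-3
sb236057a,SB236057A,,active,4.63,4,-,,NA,NA,,Low,
gw473178e,GW473178E,,active,4.79,4,-,,NA,NA,,Low,
ssr241586,SSR241586,,active,4.86,3,-,,Limited,Yes,,High,
ssr69071,SSR69071,,active,5.05,4,-,,NA,NA,,Low,
mevinphos,Mevinphos,COP(=O)(OC)O/C(C)=C/C(=O)OC,active,5.11,3,+-,,Yes,Yes,,High,CAS:7786-34-7
azamethiphos,Azamethiphos,COP(=O)(OC)SCN1C(=O)Oc2cc(Cl)cnc21,active,6.6,2,+-,,Yes,Yes,,High,CAS:35575-96-3
oxamyl,Oxamyl,CNC(=O)O/N=C(\SC)C(=O)N(C)C,active,7.4,2,-,,Yes,Yes,,High,CAS:23135-22-0
gentian_violet,Gentian violet,[Cl-].CN(C)c1ccc(cc1)C(c1ccc(N(C)C)cc1)=C1C=CC(C=C1)=[N+](C)C,active,7.65,1,+,,Yes,Yes,TRUE,High,CAS:548-62-9
toluene_24_diisocyanate,"Toluene-2,4-diisocyanate",Cc1ccc(N=C=O)cc1N=C=O,active,8.78,2,+-,,Yes,Yes,,High,CAS:584-84-9
ddac,Didecyldimethylammonium chloride,[Cl-].CCCCCCCCCC[N+](C)(C)CCCCCCCCCC,active,12.1,1,-,,Limited,Yes,,High,CAS:7173-51-5
propoxur,Propoxur,CNC(=O)Oc1ccccc1OC(C)C,active,12.7,1,+-,,Yes,Yes,,High,CAS:114-26-1
methomyl,Methomyl,CNC(=O)O/N=C(\C)SC,active,13.9,3,-,,Yes,Yes,,High,CAS:16752-77-5
pentamidine_isethionate,Pentamidine isethionate,NC(=N)c1ccc(OCCCCCOc2ccc(C(N)=N)cc2)cc1.OCCS(=O)(=O)O,active,16.8,2,NA,,Limited,No,,Low,CAS:140-64-7
bis2ethylhexyl_decandioate,bis(2-Ethylhexyl) decandioate,CCCCC(CC)COC(=O)CCCCCCCCC(=O)OCC(CC)CCCC,active,17,4,=,,NA,NA,,Low,CAS:122-62-3
sr125047,SR125047,,active,17.6,4,-,,NA,NA,,Low,
pharmagsid_48172,PharmaGSID_48172,,active,18.3,4,-,,NA,NA,,Low,
dodecylbenzenesulfonic_acid,Dodecylbenzenesulfonic acid,CCCCCCCCCCCCc1ccc(cc1)S(=O)(=O)O,active,19.3,1,+-,,Limited,Yes,,High,CAS:27176-87-0
ssr150106,SSR150106,,active,20.9,3,+,,Yes,Yes,,High,
mercuric_chloride,Mercuric chloride,Cl[Hg]Cl,active,23.1,2,+,,Yes,Yes,,High,CAS:7487-94-7
bronopol,Bronopol,OCC(Br)(CO)[N+](=O)[O-],active,23.3,1,+-,,Yes,Yes,,High,CAS:52-51-7
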