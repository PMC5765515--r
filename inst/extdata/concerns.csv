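concern_id,substance,product_names,index_date,concern_type,grouping_level,grouping_id
C01,human normal immunoglobulin,octagam,2010-08-23,QD,SMQ,embolic and thrombotic events
C02,heparin,heparin rotexmedica,2008-02-18,QD,SMQ,anaphylactic reactions
C02,heparin,heparin rotexmedica,2008-02-18,QD,SMQ,hypersensitivity
C03,peritoneal dialysis solutions,baxter extraneal;baxter nutrineal;baxter dianeal,2010-10-16,QD,HLT,abdominal and gastrointestinal infections
C03,peritoneal dialysis solutions,baxter extraneal;baxter nutrineal;baxter dianeal,2010-10-16,QD,HLT,peritoneal infections and febrile disorders
C04,epinephrine,jext,2013-11-07,QD,SMQ,anaphylactic reactions
C04,epinephrine,jext,2013-11-07,QD,SMQ,lack of efficacy/effect
C04,epinephrine,jext,2013-11-07,QD,HLGT,product use issues
C05,insulin aspart,novomix,2013-10-24,QD,HLGT,glucose metabolism disorders (incl. diabetes mellitus)
C05,insulin aspart,novomix,2013-10-24,QD,SMQ,hyperglycaemia/new onset diabetes mellitus
C05,insulin aspart,novomix,2013-10-24,QD,SMQ,hypoglycaemia
C05,insulin aspart,novomix,2013-10-24,QD,HLGT,product use issues
C05,insulin aspart,novomix,2013-10-24,QD,SMQ,lack of efficacy/effect
C06,fibrinogen-containing sealant solutions,evecil;quixil,2010-06-21,ME,SMQ,medication errors
C06,fibrinogen-containing sealant solutions,evecil;quixil,2010-06-21,ME,HLT,non-site specific embolism and thrombosis
C06,fibrinogen-containing sealant solutions,evecil;quixil,2010-06-21,ME,HLGT,product use issues
C07,levetiracetam,keppra,2015-12-22,ME,SMQ,medication errors
C07,levetiracetam,keppra,2015-12-22,ME,HLGT,neurological disorders nec
C07,levetiracetam,keppra,2015-12-22,ME,HLGT,product use issues
C08,cabazitaxel,jevtana,2013-09-16,ME,SMQ,medication errors
C08,cabazitaxel,jevtana,2013-09-16,ME,HLGT,product use issues
C09,adalimumab,humira,2013-09-13,ME,SMQ,medication errors
C09,adalimumab,humira,2013-09-13,ME,HLGT,product use issues
C10,leuprorelin,eligard,2013-11-06,ME,SMQ,medication errors
C10,leuprorelin,eligard,2013-11-06,ME,HLGT,product use issues
C11,loperamide,,2015-04-23,AM,SMQ,medication errors
C11,loperamide,,2015-04-23,AM,HLGT,product use issues
C11,loperamide,,2015-04-23,AM,HLT,substance-related disorders
C11,loperamide,,2015-04-23,AM,SMQ,drug abuse and dependence
C11,loperamide,,2015-04-23,AM,SMQ,torsade de pointes/qt prolongation
C12,buprenorphine,,2013-03-21,AM,HLT,substance-related disorders
C12,buprenorphine,,2013-03-21,AM,SMQ,drug abuse and dependence
C13,melatonin,,2011-10-17,AM,SMQ,drug abuse and dependence
C13,melatonin,,2011-10-17,AM,SMQ,psychosis and psychotic disorders
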