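sample	day	side	separation	fused_day10
R001	10	left	4.40273771901161	FALSE
R001	25	left	7.39371618131067	FALSE
R001	42	left	9.23546832287006	FALSE
R001	10	right	3.96921421618221	FALSE
R001	25	right	6.05180786822843	FALSE
R001	42	right	8.11628050347478	FALSE
R002	10	left	3.97508429234248	FALSE
R002	25	left	5.82988488845185	FALSE
R002	42	left	7.27026366485415	FALSE
R002	10	right	3.44382065723975	FALSE
R002	25	right	5.03029978950012	FALSE
R002	42	right	6.27221417533773	FALSE
R003	10	left	4.24324528577105	FALSE
R003	25	left	5.74018912490232	FALSE
R003	42	left	7.28936057621714	FALSE
R003	10	right	4.45995814933646	FALSE
R003	25	right	6.11585682796784	FALSE
R003	42	right	7.49036573594961	FALSE
R004	10	left	4.34255068038037	FALSE
R004	25	left	6.48273234175833	FALSE
R004	42	left	8.17735104620651	FALSE
R004	10	right	4.24962635949981	FALSE
R004	25	right	6.28538652740744	FALSE
R004	42	right	8.06143313322513	FALSE
R005	10	left	4.23721912331689	TRUE
R005	25	left	4.23721912331689	TRUE
R005	42	left	4.23721912331689	TRUE
R005	10	right	4.05209682397267	TRUE
R005	25	right	4.05209682397267	TRUE
R005	42	right	4.05209682397267	TRUE
R006	10	left	4.04129943548573	FALSE
R006	25	left	5.65752720968266	FALSE
R006	42	left	7.41388978210484	FALSE
R006	10	right	4.44644905881086	FALSE
R006	25	right	6.238774337086	FALSE
R006	42	right	7.45011029212182	FALSE
R007	10	left	3.59180132772277	FALSE
R007	25	left	5.47651736960829	FALSE
R007	42	left	6.86508882526976	FALSE
R007	10	right	3.90548343695302	FALSE
R007	25	right	5.64290290922112	FALSE
R007	42	right	7.34862180916107	FALSE
R008	10	left	4.15391612382849	FALSE
R008	25	left	6.57704180897424	FALSE
R008	42	left	7.93137118037195	FALSE
R008	10	right	4.38662097176902	FALSE
R008	25	right	7.03756104716057	FALSE
R008	42	right	9.07011138287766	FALSE
R009	10	left	4.06486196767499	FALSE
R009	25	left	6.35566497589518	FALSE
R009	42	left	8.32761103527704	FALSE
R009	10	right	3.37101516335086	FALSE
R009	25	right	5.84936050982592	FALSE
R009	42	right	7.7256795020455	FALSE
R010	10	left	3.62758428637054	TRUE
R010	25	left	3.62758428637054	TRUE
R010	42	left	3.62758428637054	TRUE
R010	10	right	4.35858926908517	TRUE
R010	25	right	4.35858926908517	TRUE
R010	42	right	4.35858926908517	TRUE
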