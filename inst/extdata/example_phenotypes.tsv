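sample	diagnosis	sire	dam
R001	ICN		
R002	DOS		
R003	DOS		
R004	ICN		
R005	EOS		
R006	DOS		
R007	DOS	R002	R006
R008	ICN	R002	R006
R009	ICN	R002	R006
R010	EOS	R002	R006
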