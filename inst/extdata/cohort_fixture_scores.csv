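report_id,assessor_id,prev_adr_history,actual_reaction,key_events,suspected_medications,timeline,management,outcome_sequelae
R001,primary,0,0,0,0,0,1,2
R002,primary,0,0,0,0,1,1,0
R003,primary,0,0,0,0,0,1,2
R004,primary,1,2,1,1,1,1,2
R005,primary,2,1,1,1,1,1,2
R006,primary,2,2,1,1,1,0,2
R007,primary,1,2,2,1,1,1,1
R008,primary,2,1,1,2,1,1,2
R009,primary,2,2,2,1,0,1,2
R010,primary,2,2,2,2,1,0,2
R011,primary,2,2,2,2,1,1,1
R012,primary,2,2,2,2,1,1,2
R013,primary,2,2,2,2,1,1,2
R014,primary,2,2,2,2,1,1,2
R015,primary,2,2,2,2,1,1,2
R016,primary,2,2,2,2,1,1,2
R017,primary,2,2,2,2,1,1,2
R018,primary,2,2,2,2,1,1,2
R019,primary,2,2,2,2,1,1,2
R020,primary,2,2,2,2,1,1,2
R021,primary,0,0,0,0,1,0,2
R022,primary,0,0,0,0,0,1,2
R023,primary,0,0,0,0,1,0,2
R024,primary,1,1,1,1,1,1,2
R025,primary,1,1,1,1,1,1,2
R026,primary,2,1,1,1,1,1,1
R027,primary,1,1,1,1,1,1,2
R028,primary,2,1,1,1,1,1,2
R029,primary,2,1,1,1,1,1,2
R030,primary,2,1,1,1,1,1,2
R031,primary,2,1,1,1,1,1,2
R032,primary,2,2,1,1,1,1,2
R033,primary,2,2,1,1,1,1,2
R034,primary,2,2,1,1,1,1,2
R035,primary,2,2,1,1,1,1,2
R036,primary,2,1,1,2,1,1,2
R037,primary,2,1,2,1,1,1,2
R038,primary,2,2,1,2,1,1,2
R039,primary,2,2,2,1,1,1,2
R040,primary,2,2,2,2,0,1,2
R041,primary,2,2,2,2,1,0,2
R042,primary,2,2,2,2,1,1,1
R043,primary,1,2,2,2,1,1,2
R044,primary,2,1,2,2,1,1,2
R045,primary,2,2,1,2,1,1,2
R046,primary,2,2,2,1,1,1,2
R047,primary,2,2,2,2,0,1,2
R048,primary,2,2,2,2,1,0,2
R049,primary,2,2,2,2,1,1,1
R050,primary,2,2,2,2,1,1,2
R051,primary,2,2,2,2,1,1,2
R052,primary,2,2,2,2,1,1,2
R053,primary,2,2,2,2,1,1,2
R054,primary,2,2,2,2,1,1,2
R055,primary,2,2,2,2,1,1,2
R056,primary,2,2,2,2,1,1,2
R057,primary,2,2,2,2,1,1,2
R058,primary,2,2,2,2,1,1,2
R059,primary,2,2,2,2,1,1,2
R060,primary,2,2,2,2,1,1,2
R061,primary,2,2,2,2,1,1,2
R062,primary,2,2,2,2,1,1,2
R063,primary,2,2,2,2,1,1,2
R064,primary,2,2,2,2,1,1,2
R065,primary,2,2,2,2,1,1,2
R066,primary,2,2,2,2,1,1,2
R067,primary,2,2,2,2,1,1,2
R068,primary,2,2,2,2,1,1,2
R069,primary,2,2,2,2,1,1,2
R070,primary,2,2,2,2,1,1,2
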