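"report_id","reporter_vocation","reporting_unit","reaction_type","severity","phase","medication_classes"
"R001","Pharmacist","Medical","Delayed hypersensitivity, SCAR","Moderate","development","Anaesthetic agents;Antimetabolites"
"R002","Pharmacist","Medical","Delayed hypersensitivity, SCAR","Severe","development","Antimetabolites;Antimicrobials"
"R003","Pharmacist","Medical","Non-immunological","Severe","development","Antimicrobials;Antimicrobials"
"R004","Pharmacist","Medical","Non-immunological","Life-threatening","development","Antimicrobials;Antimicrobials"
"R005","Pharmacist","Medical","Other","Life-threatening","development","Antimicrobials;Antimicrobials"
"R006","Doctor","Medical","Other","Not recorded","development","Antimicrobials;Antimicrobials"
"R007","Doctor","Medical","Other","Not recorded","development","Antimicrobials;Antimicrobials"
"R008","Pharmacist","Medical","Immediate hypersensitivity","Mild","development","Antimicrobials;Antimicrobials"
"R009","Pharmacist","Medical","Immediate hypersensitivity","Moderate","development","Antimicrobials;Antimicrobials"
"R010","Pharmacist","Medical","Immediate hypersensitivity","Moderate","development","Antimicrobials;Antimicrobials"
"R011","Pharmacist","Medical","Immediate hypersensitivity","Moderate","development","Antimicrobials;Antimicrobials"
"R012","Pharmacist","Medical","Delayed hypersensitivity, non-SCAR","Moderate","development","Antimicrobials"
"R013","Pharmacist","Surgical","Delayed hypersensitivity, non-SCAR","Moderate","development","Antimicrobials"
"R014","Pharmacist","Surgical","Delayed hypersensitivity, single-organ involvement","Moderate","development","Antimicrobials"
"R015","Pharmacist","Surgical","Delayed hypersensitivity, single-organ involvement","Moderate","development","Antimicrobials"
"R016","Pharmacist","Surgical","Delayed hypersensitivity, SCAR","Moderate","development","Antimicrobials"
"R017","Pharmacist","Surgical","Delayed hypersensitivity, SCAR","Moderate","development","Opioids"
"R018","Pharmacist","Other","Delayed hypersensitivity, SCAR","Moderate","development","Opioids"
"R019","Pharmacist","Other","Non-immunological","Moderate","development","Opioids"
"R020","Pharmacist","Other","Non-immunological","Life-threatening","development","Radiocontrast agents"
"R021","Pharmacist","Medical","Immediate hypersensitivity","Mild","evaluation","Anaesthetic agents;Anaesthetic agents"
"R022","Pharmacist","Medical","Immediate hypersensitivity","Mild","evaluation","Antiemetics;Antiepileptics"
"R023","Pharmacist","Medical","Immediate hypersensitivity","Mild","evaluation","Antiepileptics;Antiepileptics"
"R024","Pharmacist","Medical","Immediate hypersensitivity","Mild","evaluation","Antihypertensives;Antihypertensives"
"R025","Pharmacist","Medical","Immediate hypersensitivity","Moderate","evaluation","Antimetabolites;Antimetabolites"
"R026","Pharmacist","Medical","Immediate hypersensitivity","Moderate","evaluation","Antimetabolites;Antimicrobials"
"R027","Pharmacist","Medical","Delayed hypersensitivity, non-SCAR","Moderate","evaluation","Antimicrobials;Antimicrobials"
"R028","Pharmacist","Medical","Delayed hypersensitivity, non-SCAR","Severe","evaluation","Antimicrobials;Antimicrobials"
"R029","Pharmacist","Medical","Delayed hypersensitivity, non-SCAR","Fatal","evaluation","Antimicrobials;Antimicrobials"
"R030","Pharmacist","Medical","Delayed hypersensitivity, non-SCAR","Not recorded","evaluation","Antimicrobials;Antimicrobials"
"R031","Doctor","Medical","Delayed hypersensitivity, SCAR","Not recorded","evaluation","Antimicrobials;Antimicrobials"
"R032","Pharmacist","Medical","Immediate hypersensitivity","Mild","evaluation","Antimicrobials;Antimicrobials"
"R033","Pharmacist","Medical","Immediate hypersensitivity","Mild","evaluation","Antimicrobials;Antimicrobials"
"R034","Pharmacist","Medical","Immediate hypersensitivity","Moderate","evaluation","Antimicrobials;Antimicrobials"
"R035","Pharmacist","Medical","Delayed hypersensitivity, non-SCAR","Moderate","evaluation","Antimicrobials;Antimicrobials"
"R036","Pharmacist","Medical","Delayed hypersensitivity, non-SCAR","Moderate","evaluation","Antimicrobials;Antimicrobials"
"R037","Pharmacist","Medical","Delayed hypersensitivity, non-SCAR","Moderate","evaluation","Antimicrobials;Antimicrobials"
"R038","Pharmacist","Medical","Delayed hypersensitivity, non-SCAR","Moderate","evaluation","Antimicrobials;Antimicrobials"
"R039","Pharmacist","Medical","Delayed hypersensitivity, non-SCAR","Moderate","evaluation","Antimicrobials;Antimicrobials"
"R040","Pharmacist","Medical","Delayed hypersensitivity, non-SCAR","Moderate","evaluation","Antimicrobials;Antimicrobials"
"R041","Pharmacist","Medical","Delayed hypersensitivity, non-SCAR","Moderate","evaluation","Antimicrobials;Antimicrobials"
"R042","Pharmacist","Medical","Delayed hypersensitivity, non-SCAR","Moderate","evaluation","Antimicrobials;Antimicrobials"
"R043","Pharmacist","Medical","Delayed hypersensitivity, non-SCAR","Moderate","evaluation","Antimicrobials;Antimicrobials"
"R044","Pharmacist","Medical","Delayed hypersensitivity, non-SCAR","Moderate","evaluation","Antimicrobials;Antimicrobials"
"R045","Pharmacist","Medical","Delayed hypersensitivity, non-SCAR","Moderate","evaluation","Antimicrobials;Antimicrobials"
"R046","Pharmacist","Surgical","Delayed hypersensitivity, non-SCAR","Moderate","evaluation","Antimicrobials;Antimicrobials"
"R047","Pharmacist","Surgical","Delayed hypersensitivity, single-organ involvement","Moderate","evaluation","Antimicrobials;Antimicrobials"
"R048","Pharmacist","Surgical","Delayed hypersensitivity, single-organ involvement","Moderate","evaluation","Antimicrobials;Antimicrobials"
"R049","Pharmacist","Surgical","Delayed hypersensitivity, single-organ involvement","Moderate","evaluation","Antimicrobials;Iron formulations"
"R050","Pharmacist","Surgical","Delayed hypersensitivity, single-organ involvement","Moderate","evaluation","Iron formulations;NSAIDs"
"R051","Pharmacist","Surgical","Delayed hypersensitivity, single-organ involvement","Moderate","evaluation","NSAIDs;NSAIDs"
"R052","Pharmacist","Surgical","Delayed hypersensitivity, single-organ involvement","Severe","evaluation","Opioids"
"R053","Pharmacist","Surgical","Delayed hypersensitivity, single-organ involvement","Severe","evaluation","Radiocontrast agents"
"R054","Pharmacist","Surgical","Delayed hypersensitivity, single-organ involvement","Severe","evaluation","Radiocontrast agents"
"R055","Pharmacist","ED","Delayed hypersensitivity, single-organ involvement","Severe","evaluation","Radiocontrast agents"
"R056","Pharmacist","ED","Delayed hypersensitivity, single-organ involvement","Severe","evaluation","Others"
"R057","Pharmacist","ED","Delayed hypersensitivity, single-organ involvement","Severe","evaluation","Others"
"R058","Pharmacist","ED","Delayed hypersensitivity, single-organ involvement","Severe","evaluation","Others"
"R059","Pharmacist","ED","Delayed hypersensitivity, SCAR","Severe","evaluation","Others"
"R060","Pharmacist","ED","Delayed hypersensitivity, SCAR","Severe","evaluation","Others"
"R061","Pharmacist","ED","Delayed hypersensitivity, SCAR","Severe","evaluation","Others"
"R062","Pharmacist","ED","Delayed hypersensitivity, SCAR","Severe","evaluation","Others"
"R063","Pharmacist","ED","Non-immunological","Severe","evaluation","Others"
"R064","Doctor","ED","Non-immunological","Severe","evaluation","Others"
"R065","Doctor","Other","Non-immunological","Life-threatening","evaluation","Others"
"R066","Doctor","Other","Other","Life-threatening","evaluation","Others"
"R067","Doctor","Other","Other","Life-threatening","evaluation","Others"
"R068","Doctor","Other","Other","Life-threatening","evaluation","Others"
"R069","Doctor","Other","Other","Fatal","evaluation","Others"
"R070","Doctor","Other","Other","Not recorded","evaluation","Others"
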