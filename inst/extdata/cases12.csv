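case_id,youth_id,cms_id,county_id,extraction_phase,gender,race_ethnicity,age,charge_severity,diverted,detained,petitioned,adjudicated,probation,confined,waived
C000001,Y00001,CMS1,CMS1-1,PRE,male,White,14,Misdemeanor A,yes,no,no,no,no,no,no
C000002,Y00001,CMS1,CMS1-1,PRE,male,White,14,Felony D,no,no,yes,yes,yes,no,no
C000003,Y00002,CMS1,CMS1-2,PRE,female,African American/Black,16,Misdemeanor B,yes,no,yes,no,no,no,yes
C000004,Y00003,CMS1,CMS1-1,PRE,male,White,15,Status Offense,no,yes,no,no,no,no,no
C000005,Y00004,CMS2,CMS2-1,PRE,male,Hispanic/Latino,17,Felony C,yes,no,no,no,no,yes,no
C000006,Y00005,CMS2,CMS2-2,PRE,female,White,17,Felony B,no,no,yes,yes,no,no,yes
C000007,Y00006,CMS2,CMS2-1,PRE,male,White,13,Misdemeanor A,no,no,yes,no,yes,no,no
C000008,Y00007,CMS3,CMS3-1,PRE,female,Other,15,Status Offense,,no,no,no,no,no,no
C000009,Y00008,CMS3,CMS3-3,PRE,male,White,16,Misdemeanor C,no,no,yes,yes,no,no,Y3S
C000010,Y00009,CMS3,CMS3-2,PRE,male,African American/Black,12,Status Offense,no,no,yes,no,no,no,no
C000011,Y00010,CMS4,CMS4-1,PRE,female,,16,,no,no,yes,no,no,yes,no
C000012,Y00011,CMS4,CMS4-2,PRE,male,,11,,yes,yes,no,no,no,no,no
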