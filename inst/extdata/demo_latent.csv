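record_id,cluster
r0000001,prostate_cancer
r0000002,poisoning
r0000003,cardiovascular
r0000004,cardiovascular
r0000005,other_cancer
r0000006,stroke
r0000007,uro_gi_infection
r0000008,prostate_cancer
r0000009,other_cancer
r0000010,open_wound_suffocation
r0000011,other_cancer
r0000012,other_cancer
r0000013,stroke
r0000014,cardiovascular
r0000015,open_wound_suffocation
r0000016,cardiovascular
r0000017,respiratory
r0000018,cardiovascular
r0000019,prostate_cancer
r0000020,uro_gi_infection
r0000021,other_physical_harm
r0000022,uro_gi_infection
r0000023,prostate_cancer
r0000024,diabetes_renal
r0000025,prostate_cancer
r0000026,cardiovascular
r0000027,other_physical_harm
r0000028,open_wound_suffocation
r0000029,prostate_cancer
r0000030,poisoning
r0000031,geriatric
r0000032,uro_gi_infection
r0000033,other_cancer
r0000034,other_cancer
r0000035,poisoning
r0000036,gi_cancer
r0000037,open_wound_suffocation
r0000038,stroke
r0000039,gi_cancer
r0000040,open_wound_suffocation
r0000041,hypertensive
r0000042,poisoning
r0000043,stroke
r0000044,open_wound_suffocation
r0000045,diabetes_renal
r0000046,uro_gi_infection
r0000047,cardiovascular
r0000048,hypertensive
r0000049,lung_cancer
r0000050,liver
r0000051,respiratory
r0000052,geriatric
r0000053,stroke
r0000054,other_physical_harm
r0000055,cardiac_acute
r0000056,poisoning
r0000057,other_cancer
r0000058,other_cancer
r0000059,poisoning
r0000060,uro_gi_infection
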