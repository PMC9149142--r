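SubjID,Sex,SANS01,SANS02,SANS03,SANS04,SANS05,SANS06,SANS07,SANS08,SANS09,SANS10,SANS11,SANS12,SANS13,SANS14,SANS15,SANS16,SANS17,SANS18,SANS19,SANS20,SANS21,SANS22,SANS23,SANS24,SANS25,AgeinYears,IllnessYears
example_S001,male,2,2,1,2,1,2,2,2,2,3,1,2,1,2,1,1,3,2,2,2,1,2,2,2,1,40,13
example_S002,male,1,2,0,1,1,1,2,2,1,2,2,2,1,2,1,1,2,1,1,1,1,1,1,2,1,32,3
example_S003,male,0,0,1,1,1,1,0,1,1,1,1,1,0,1,1,1,0,0,2,0,1,2,1,2,2,33,19
example_S004,male,0,1,1,1,1,1,1,0,1,1,0,1,1,1,1,1,1,1,1,1,1,0,0,1,1,24,14
example_S005,female,1,1,2,1,2,1,2,1,2,3,2,2,2,2,2,3,2,2,2,2,2,2,2,3,2,29,11
example_S006,female,2,2,2,2,2,2,2,1,2,2,1,2,1,2,1,2,3,2,3,2,2,3,3,3,1,50,18
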