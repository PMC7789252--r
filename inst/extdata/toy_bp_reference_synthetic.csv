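sex,age,height_percentile,sbp_p90,dbp_p90
male,9,0,109.5,71.75
male,9,25,110,72
male,9,50,110.5,72.25
male,9,75,111,72.5
male,9,100,111.5,72.75
male,10,0,111,72.25
male,10,25,111.5,72.5
male,10,50,112,72.75
male,10,75,112.5,73
male,10,100,113,73.25
male,11,0,112.5,72.75
male,11,25,113,73
male,11,50,113.5,73.25
male,11,75,114,73.5
male,11,100,114.5,73.75
male,12,0,114,73.25
male,12,25,114.5,73.5
male,12,50,115,73.75
male,12,75,115.5,74
male,12,100,116,74.25
male,13,0,115.5,73.75
male,13,25,116,74
male,13,50,116.5,74.25
male,13,75,117,74.5
male,13,100,117.5,74.75
female,9,0,108.5,71.25
female,9,25,109,71.5
female,9,50,109.5,71.75
female,9,75,110,72
female,9,100,110.5,72.25
female,10,0,110,71.75
female,10,25,110.5,72
female,10,50,111,72.25
female,10,75,111.5,72.5
female,10,100,112,72.75
female,11,0,111.5,72.25
female,11,25,112,72.5
female,11,50,112.5,72.75
female,11,75,113,73
female,11,100,113.5,73.25
female,12,0,113,72.75
female,12,25,113.5,73
female,12,50,114,73.25
female,12,75,114.5,73.5
female,12,100,115,73.75
female,13,0,114.5,73.25
female,13,25,115,73.5
female,13,50,115.5,73.75
female,13,75,116,74
female,13,100,116.5,74.25
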