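"patient_id","ttd_minutes","era_year"
"P00001",55.62,2022
"P00002",0.37,2016
"P00003",0.2,2019
"P00004",922.86,2015
"P00005",30.37,2022
"P00006",0.77,2018
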