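"patient_id","variable","value"
"P00001","age",88
"P00001","bmi",25.8
"P00001","dialysis",0
"P00001","sex",1
"P00001","weight",71.5
"P00002","age",85
"P00002","bmi",31.54
"P00002","dialysis",0
"P00002","sex",0
"P00002","weight",104.5
"P00003","age",54
"P00003","bmi",41.53
"P00003","dialysis",0
"P00003","sex",0
"P00003","weight",118.3
"P00004","age",65
"P00004","bmi",26.2
"P00004","dialysis",0
"P00004","sex",0
"P00004","weight",79.4
"P00005","age",76
"P00005","bmi",29.59
"P00005","dialysis",1
"P00005","sex",0
"P00005","weight",93.4
"P00006","age",54
"P00006","bmi",19.51
"P00006","dialysis",0
"P00006","sex",0
"P00006","weight",59.3
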