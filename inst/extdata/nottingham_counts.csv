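"stratum","mode","round","observed","predicted"
"participant","prevalent_normal",1,44733,44735.42
"participant","prevalent_crc",1,104,101.58
"participant","positive_unconfirmed_first",1,28,27.76
"participant","positive_unconfirmed_repeat",,57,66.03
"participant","interval_crc",,164,140.04
"participant","repeat_normal",,88008,87977.51
"participant","repeat_crc",,132,109.69
"refuser","refuser_normal",,30015,30014.06
"refuser","refuser_crc",,400,400.94
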