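"stratum","mode","round","observed","predicted"
"participant","prevalent_normal",1,20635,20630.24
"participant","prevalent_crc",1,37,41.76
"participant","interval_crc",,148,147.23
"participant","repeat_normal",,66025,66014.12
"participant","repeat_crc",,83,67.74
"refuser","refuser_normal",,9895,9895.71
"refuser","refuser_crc",,195,194.29
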