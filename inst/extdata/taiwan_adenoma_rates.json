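{"lambda2":0.53,"sens_crc":0.8286,"lambda1a":0.00149,"lambda1b":0.0839,"sens_adenoma":0.6348}
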