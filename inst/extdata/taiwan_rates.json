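{"lambda1":0.00141,"lambda2":0.386,"sens_crc":0.8025}
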