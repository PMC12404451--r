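{"num": [0.0141, 0.06238, -0.07216, 0.2293, -0.07586], "den": [1, -0.6273, 0.442, -0.3457, 0.1437], "dt": null}
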