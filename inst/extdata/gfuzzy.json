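{"num": [0.5055, -0.4212, 0.01324, 0.02104, 0.05695], "den": [1, -0.2329, 0.1049, -0.1606, 0.1928], "dt": null}
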