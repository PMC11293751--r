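{
  "comment": "Resolved block configuration of the lightweight classifier. Frozen: for 256x256x1 input this sequence counts 549890 trainable and 3904 non-trainable parameters (553794 total). Filter lists: conv/identity blocks (F1,F2,F3); inception blocks (F1..F6); stem/head a single filter count.",
  "input_shape": [256, 256],
  "blocks": {
    "kind": ["stem", "conv_block", "identity_block", "identity_block",
             "conv_block", "identity_block", "identity_block",
             "identity_block", "identity_block",
             "inception_block", "inception_block", "head"],
    "stride": [2, 1, 1, 1, 2, 1, 1, 1, 1, 1, 1, 1]
  },
  "filters": [
    [32],
    [32, 32, 64],
    [32, 32, 64],
    [32, 32, 64],
    [64, 64, 128],
    [64, 64, 128],
    [64, 64, 128],
    [64, 64, 128],
    [64, 64, 128],
    [32, 64, 96, 16, 32, 32],
    [64, 64, 128, 16, 64, 32],
    [64]
  ]
}
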