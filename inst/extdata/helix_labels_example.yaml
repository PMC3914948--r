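# Example helix label map: label -> inclusive 1-based 5'-strand range.
# A helix receives the label when its 5' range overlaps the given range.
"Helix 2": [17, 19]
"Helix 26a": [601, 620]
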