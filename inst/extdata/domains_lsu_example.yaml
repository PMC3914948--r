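# Example LSU rRNA domain scheme (Domain 0 and I-VI plus 5.8S/5S) with
# the conventional map colors.  The residue ranges below are
# ILLUSTRATIVE placeholders scaled to a small index space — real LSU
# domain boundaries are structure- and species-specific and must be
# supplied by the user for a real 23S/28S chain.
domains:
  - name: "Domain 0"
    color: orange
    ranges: [[1, 60]]
  - name: "I"
    color: purple
    ranges: [[61, 160]]
  - name: "II"
    color: blue
    ranges: [[161, 300]]
  - name: "III"
    color: magenta
    ranges: [[301, 380]]
  - name: "IV"
    color: yellow
    ranges: [[381, 480]]
  - name: "V"
    color: pink
    ranges: [[481, 600]]
  - name: "VI"
    color: green
    ranges: [[601, 660]]
  - name: "5.8S"
    color: brown
    ranges: [[661, 700]]
  - name: "5S"
    color: lightgreen
    ranges: [[701, 740]]
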