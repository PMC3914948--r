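# Example SSU rRNA domain scheme (5', Central, 3' Major, 3' minor) with
# the conventional map colors.  Ranges are ILLUSTRATIVE placeholders —
# real 16S/18S domain boundaries must be supplied by the user.
domains:
  - name: "5'"
    color: blue
    ranges: [[1, 250]]
  - name: "C"
    color: brown
    ranges: [[251, 500]]
  - name: "3'M"
    color: pink
    ranges: [[501, 800]]
  - name: "3'm"
    color: green
    ranges: [[801, 920]]
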