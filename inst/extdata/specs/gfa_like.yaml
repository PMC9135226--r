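# Tabular assembly-graph subset (GFA1-like): header (H), segment (S) and
# link (L) records, '#' comments, and name:type:value tags whose type code
# selects the value datatype.  This is a representative subset of the full
# format, sufficient for section structure and tag-system behaviour
# (including repairing files with invalid tag type codes via an import
# override).
datatypes:

  segment_name:
    regex: "[A-Za-z0-9_.-]+"

  orientation:
    values: ["+", "-"]

  # "*" (sequence not stored) decodes to null
  sequence:
    one_of:
      - constant: "*"
        decoded: {"*": ~}
      - regex: "[A-Za-z=.]+"

  cigar:
    one_of:
      - constant: "*"
        decoded: {"*": ~}
      - regex: "([0-9]+[MIDNSHP=X])+"

  # tag value datatypes by type code; the decoded tag keeps the value
  # only, and encoding picks the first type code able to represent it
  # (A before Z: single characters re-encode as A)
  tags:
    tagged_list:
      A: {regex: "[!-~]"}
      i: {integer: {}}
      f: {float: {}}
      Z: {regex: "[ !-~]*"}
    tagname: "[A-Za-z][A-Za-z0-9]"
    internal_separator: ":"
    splitted_by: "\t"

  header_line:
    composed_of:
      - record_type: {constant: "H"}
      - tags: tags
    n_required: 1
    splitted_by: "\t"

  segment_line:
    composed_of:
      - record_type: {constant: "S"}
      - name: segment_name
      - sequence: sequence
      - tags: tags
    n_required: 3
    splitted_by: "\t"

  link_line:
    composed_of:
      - record_type: {constant: "L"}
      - from: segment_name
      - from_orient: orientation
      - to: segment_name
      - to_orient: orientation
      - overlap: cigar
      - tags: tags
    n_required: 6
    splitted_by: "\t"

  comment:
    regex: "#.*"

  line:
    one_of:
      - comment
      - header_line
      - segment_line
      - link_line
    scope: line

testdata:
  sequence:
    valid:
      "*": ~
      "ACGT": "ACGT"
    invalid: ["", "AC GT", "AC*GT"]
  tags:
    valid:
      "VN:Z:1.0":
        VN: "1.0"
      "LN:i:42\tSH:A:x":
        LN: 42
        SH: "x"
      "RC:f:1.5":
        RC: 1.5
    invalid:
      - "VN:z:1.0"
      - "VN:Z"
      - "toolong:Z:x"
      - "LN:i:4.5"
  segment_line:
    valid:
      "S\ts1\tACGT":
        record_type: "S"
        name: "s1"
        sequence: "ACGT"
      "S\ts2\t*\tLN:i:100":
        record_type: "S"
        name: "s2"
        sequence: ~
        tags: {LN: 100}
    invalid:
      - "S\ts1"
      - "S\ts1\tACGT\tXX:q:1"
  line:
    valid:
      "# comment": "# comment"
      "L\ts1\t+\ts2\t-\t10M":
        record_type: "L"
        from: "s1"
        from_orient: "+"
        to: "s2"
        to_orient: "-"
        overlap: "10M"
    invalid:
      - "Q\tx"
      - "L\ts1\t+\ts2"
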