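# Header/alignment two-section tabular subset (SAM-like): a required
# header section ('@' lines) followed by alignment lines.  The whole-file
# datatype has file scope, so decoding a file validates the global
# structure (an alignment before the header is a structural error), while
# streaming still processes one line at a time.  The alignment schema is a
# reduced subset (qname, flag, rname, pos, mapq, seq, tags).
datatypes:

  header_tag:
    regex: "@[A-Z]{2}"

  header_field:
    regex: "[ -~]+"

  header_fields:
    list_of: header_field
    min_length: 1
    splitted_by: "\t"

  header_line:
    composed_of:
      - tag: header_tag
      - fields: header_fields
    splitted_by: "\t"

  qname:
    regex: "[!-?A-~]+"

  flag:
    unsigned_integer: {min: 0, max: 4095}

  rname:
    one_of:
      - constant: "*"
        decoded: {"*": ~}
      - regex: "[A-Za-z0-9_.-]+"

  pos:
    integer: {min: 0}

  mapq:
    integer: {min: 0, max: 255}

  seq:
    one_of:
      - constant: "*"
        decoded: {"*": ~}
      - regex: "[A-Za-z=.]+"

  tags:
    tagged_list:
      A: {regex: "[!-~]"}
      i: {integer: {}}
      f: {float: {}}
      Z: {regex: "[ !-~]*"}
    tagname: "[A-Za-z][A-Za-z0-9]"
    internal_separator: ":"
    splitted_by: "\t"

  alignment_line:
    composed_of:
      - qname: qname
      - flag: flag
      - rname: rname
      - pos: pos
      - mapq: mapq
      - seq: seq
      - tags: tags
    n_required: 6
    splitted_by: "\t"

  header_section:
    list_of: header_line
    min_length: 1
    splitted_by: "\n"

  alignment_section:
    list_of: alignment_line
    min_length: 0
    splitted_by: "\n"

  file:
    composed_of:
      - header: header_section
      - alignments: alignment_section
    splitted_by: "\n"
    scope: file

testdata:
  header_line:
    valid:
      "@HD\tVN:1.6":
        tag: "@HD"
        fields: ["VN:1.6"]
      "@SQ\tSN:ref1\tLN:10000":
        tag: "@SQ"
        fields: ["SN:ref1", "LN:10000"]
    invalid: ["@H\tx", "HD\tVN:1.6", "@HD"]
  alignment_line:
    valid:
      "read1\t0\tref1\t100\t60\tACGT":
        qname: "read1"
        flag: 0
        rname: "ref1"
        pos: 100
        mapq: 60
        seq: "ACGT"
      "read2\t16\t*\t0\t0\t*\tNM:i:2":
        qname: "read2"
        flag: 16
        rname: ~
        pos: 0
        mapq: 0
        seq: ~
        tags: {NM: 2}
    invalid:
      - "read1\t-1\tref1\t100\t60\tACGT"
      - "read1\t0\tref1\t100\t300\tACGT"
      - "read1\t0\tref1"
  flag:
    valid:
      "0": 0
      "4095": 4095
    invalid: ["4096", "-1", "x"]
  mapq:
    valid:
      "0": 0
      "255": 255
    invalid: ["256", "-1", "60.5"]
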