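# FASTA: header lines (">" + identifier + optional description words) and
# sequence lines; decoded line by line (a one_of over the two line types),
# since entries span a variable number of lines.
datatypes:

  seq_id:
    regex: "[!-~]+"

  word:
    regex: "[!-~]+"

  description:
    list_of: word
    min_length: 1
    splitted_by: " "

  header:
    composed_of:
      - id: seq_id
      - desc: description
    n_required: 1
    splitted_by: " "
    prefix: ">"

  sequence_line:
    regex: "[A-Za-z*\\-]+"

  line:
    one_of:
      - header
      - sequence_line
    scope: line

testdata:
  header:
    valid:
      ">chr1":
        id: "chr1"
      ">sp|P01013|OVAX_CHICK Ovalbumin-related protein X":
        id: "sp|P01013|OVAX_CHICK"
        desc: ["Ovalbumin-related", "protein", "X"]
    invalid: ["chr1", ">", "> leading_space"]
  sequence_line:
    valid: ["ACGTACGT", "MKVLAA*", "acgt-n"]
    invalid: ["ACGT ACGT", "", "AC>GT"]
  line:
    valid: [">chr1 human chromosome 1", "ACGTNNNACGT"]
    invalid: ["", "AC GT"]
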