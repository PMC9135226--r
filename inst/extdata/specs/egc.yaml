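# EGC (expected genomic content): tab-separated records describing rules
# about the expected content of microbial genomes.  Lines starting with '#'
# are comments; every other line is a record whose first field is a single
# letter selecting the record type:
#   A  attribute definition (something measurable in a genome)
#   T  taxon measurement subject
#   P  phenotype-group measurement subject
#   E  expectation: subject x attribute -> expected value
# Positional fields are non-empty, contain no tabs or newlines, and use '.'
# for missing information.  The per-record field schema used here is
# illustrative (the structural rules above are the fixed part).
datatypes:

  identifier:
    regex: "[A-Za-z_][A-Za-z0-9_]*"

  # non-empty, tab-free text which is not the missing-value marker "."
  free_text:
    regex: "\\.[^\t]+|[^\t.][^\t]*"

  # "." decodes to null (missing information)
  missing:
    constant: "."
    decoded:
      ".": ~

  maybe_text:
    one_of:
      - missing
      - free_text

  rank:
    one_of:
      - missing
      - values: ["kingdom", "phylum", "class", "order", "family",
                 "genus", "species", "strain"]

  operator:
    values: ["=", "<", ">", "<=", ">=", "in"]

  comment:
    regex: "#.*"

  record_A:
    composed_of:
      - record_type: {constant: "A"}
      - id: identifier
      - name: free_text
      - computation: maybe_text
    splitted_by: "\t"

  record_T:
    composed_of:
      - record_type: {constant: "T"}
      - id: identifier
      - taxon_name: free_text
      - rank: rank
    splitted_by: "\t"

  record_P:
    composed_of:
      - record_type: {constant: "P"}
      - id: identifier
      - description: free_text
    splitted_by: "\t"

  record_E:
    composed_of:
      - record_type: {constant: "E"}
      - subject: identifier
      - attribute: identifier
      - operator: operator
      - value: maybe_text
    splitted_by: "\t"

  line:
    one_of:
      - comment
      - record_A
      - record_T
      - record_P
      - record_E
    scope: line

testdata:
  identifier:
    valid: ["gc_content", "B_subtilis", "_x1"]
    invalid: ["1abc", "a b", ""]
  missing:
    valid:
      ".": ~
    invalid: ["..", ""]
  maybe_text:
    valid:
      ".": ~
      "some free text": "some free text"
      ".hidden": ".hidden"
    invalid: ["a\tb", ""]
  operator:
    valid: ["=", "<=", "in"]
    invalid: ["==", "~", ""]
  record_A:
    valid:
      "A\tgc\tGC content\t.":
        record_type: "A"
        id: "gc"
        name: "GC content"
        computation: ~
    invalid:
      - "A\tgc"
      - "A\t1gc\tGC content\t."
      - "X\tgc\tGC content\t."
  record_E:
    valid:
      "E\tbacillus\tgc\t>\t40":
        record_type: "E"
        subject: "bacillus"
        attribute: "gc"
        operator: ">"
        value: "40"
    invalid:
      - "E\tbacillus\tgc\t~\t40"
      - "E\tbacillus"
  line:
    valid:
      "# a comment": "# a comment"
      "P\tthermophile\tgrows above 45 C":
        record_type: "P"
        id: "thermophile"
        description: "grows above 45 C"
    invalid:
      - "Z\tx\ty"
      - ""
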