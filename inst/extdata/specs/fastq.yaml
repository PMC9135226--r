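# FASTQ: four-line records (unit scope).  The record is an ordered
# composition over the four lines, using the newline as the (exclusive)
# field delimiter.  The equality of sequence and quality lengths is a
# cross-field constraint, which is a caller-side check.
datatypes:

  read_id:
    regex: "[!-~]+( [!-~]+)*"

  header:
    composed_of:
      - id: read_id
    prefix: "@"
    splitted_by: "\t"

  sequence:
    regex: "[A-Za-z.~]*"

  plus_line:
    regex: "\\+[!-~ ]*"

  quality:
    regex: "[!-~]*"

  record:
    composed_of:
      - header: header
      - sequence: sequence
      - plus: plus_line
      - quality: quality
    splitted_by: "\n"
    scope: unit
    unit_size: 4

testdata:
  header:
    valid:
      "@read1 sample=A":
        id: "read1 sample=A"
    invalid: ["read1", "@"]
  record:
    valid:
      ? "@read1\nACGT\n+\nIIII"
      : header: {id: "read1"}
        sequence: "ACGT"
        plus: "+"
        quality: "IIII"
    invalid:
      - "read1\nACGT\n+\nIIII"
      - "@read1\nACGT\nIIII"
  sequence:
    valid: ["ACGTN", "", "acgt."]
    invalid: ["AC GT", "AC\tGT"]
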