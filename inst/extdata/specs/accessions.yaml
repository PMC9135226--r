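# Accession identifiers of NCBI, DDBJ, ENA/EBI and UniProt sequence
# databases.  Grammar sources (public documentation):
#   https://www.ncbi.nlm.nih.gov/Sequin/acc.html
#   https://www.ddbj.nig.ac.jp/acc_def-e.html
#   https://www.ddbj.nig.ac.jp/prefix-e.html#dra
#   https://www.ncbi.nlm.nih.gov/books/NBK21091/ (RefSeq accession table)
#   https://www.uniprot.org/help/accession_numbers
#   https://www.ensembl.org/info/genome/stable_ids/prefixes.html
# The grammars are encoded from those pages; where a page gives only
# examples, the pattern is a conservative generalization.
datatypes:

  # INSD read archives (SRA/ERA/DRA): institution letter, R, type letter,
  # then a serial number; e.g. SRR000001, ERX123456, DRP000123
  insd_read_archive:
    composed_of:
      - institution:
          values: ["S", "E", "D"]
          decoded:
            "S": "NCBI"
            "E": "ENA/EBI"
            "D": "DDBJ"
      - archive: {constant: "R"}
      - type:
          values: ["A", "P", "R", "S", "X", "Z"]
          decoded:
            "A": "submission"
            "P": "study"
            "R": "run"
            "S": "sample"
            "X": "experiment"
            "Z": "analysis"
      - entry: {regex: "[0-9]{6,9}"}
    separator: ""

  # UniProtKB: O/P/Q + 5, or the 6/10-character new-style accessions
  uniprot:
    regex: "[OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9][A-Z][A-Z0-9]{2}[0-9]([A-Z][A-Z0-9]{2}[0-9])?"

  # Trace Archive ids: TI prefix and a serial number
  trace_archive:
    composed_of:
      - database: {constant: "TI"}
      - entry: {regex: "[0-9]{1,12}"}
    separator: ""

  # INSD assembled sequence accessions (Nucleotide 1+5 or 2+6..8,
  # Protein 3+5..7, Bulk/WGS 4-6 letters + 8-10 digits), optional version
  insd_sequence:
    regex: "([A-Z][0-9]{5}|[A-Z]{2}[0-9]{6,8}|[A-Z]{3}[0-9]{5,7}|[A-Z]{4,6}[0-9]{8,10})(\\.[0-9]+)?"

  # INSD metadata: BioProject PRJ + institution letter + letter + digits;
  # BioSample SAM + institution letter + optional letter + digits
  insd_metadata:
    one_of:
      - composed_of:
          - record_type: {constant: "PRJ", decoded: {"PRJ": "BioProject"}}
          - institution:
              values: ["N", "E", "D"]
              decoded: {"N": "NCBI", "E": "ENA/EBI", "D": "DDBJ"}
          - code: {regex: "[A-Z]"}
          - entry: {regex: "[0-9]{1,9}"}
        separator: ""
      - composed_of:
          - record_type: {constant: "SAM", decoded: {"SAM": "BioSample"}}
          - institution:
              values: ["N", "E", "D"]
              decoded: {"N": "NCBI", "E": "ENA/EBI", "D": "DDBJ"}
          - code: {regex: "[A-Z]?"}
          - entry: {regex: "[0-9]{1,9}"}
        separator: ""

  refseq_prefix:
    values: ["AC", "NC", "NG", "NT", "NW", "NZ", "NM", "NR", "XM", "XR",
             "AP", "NP", "YP", "XP", "WP"]

  # RefSeq: two-letter molecule/annotation prefix, underscore, serial
  # number, optional version
  refseq:
    composed_of:
      - prefix: refseq_prefix
      - separator_char: {constant: "_"}
      - entry: {regex: "[0-9]{6,9}"}
      - version: {regex: "\\.[0-9]+"}
    n_required: 3
    separator: ""

  # Ensembl stable ids: ENS + optional species code + feature type + 11
  # digits + optional version
  ensembl:
    regex: "ENS[A-Z]{0,4}(E|FM|G|GT|P|R|T)[0-9]{11}(\\.[0-9]+)?"

  accession:
    one_of:
      - insd_read_archive
      - uniprot
      - trace_archive
      - refseq
      - insd_metadata
      - ensembl
      - insd_sequence

testdata:
  insd_read_archive:
    valid:
      "SRR000001":
        institution: "NCBI"
        archive: "R"
        type: "run"
        entry: "000001"
      "ERX123456":
        institution: "ENA/EBI"
        archive: "R"
        type: "experiment"
        entry: "123456"
      "DRP000123":
        institution: "DDBJ"
        archive: "R"
        type: "study"
        entry: "000123"
    invalid: ["XRR000001", "SRB000001", "SRR01", "srr000001"]
  uniprot:
    valid: ["P01013", "Q90RT2", "A0A023GPI8"]
    invalid: ["P0101", "Z9999", "p01013"]
  trace_archive:
    valid:
      "TI102938":
        database: "TI"
        entry: "102938"
    invalid: ["TI", "TX102938"]
  insd_sequence:
    valid: ["U12345", "AF123456", "CAM43271.1", "AAAA01000001"]
    invalid: ["U1234", "A12345678901234", "u12345"]
  insd_metadata:
    valid:
      "PRJNA123456":
        record_type: "BioProject"
        institution: "NCBI"
        code: "A"
        entry: "123456"
      "SAMN12345678":
        record_type: "BioSample"
        institution: "NCBI"
        code: ""
        entry: "12345678"
    invalid: ["PRJ123456", "SAMX1234", "BIO1234"]
  refseq:
    valid:
      "NM_010450.1":
        prefix: "NM"
        separator_char: "_"
        entry: "010450"
        version: ".1"
      "WP_003131952":
        prefix: "WP"
        separator_char: "_"
        entry: "003131952"
    invalid: ["NM010450", "QQ_010450.1", "NM_01"]
  ensembl:
    valid: ["ENSG00000139618", "ENSMUSG00000017167.6",
            "ENST00000380152"]
    invalid: ["ENS00000139618X", "ENSG0000013961"]
  accession:
    valid: ["SRR000001", "P01013", "TI102938", "NM_010450.1",
            "PRJEB1234", "ENSG00000139618", "AF123456"]
    invalid: ["not-an-accession", "123456", ""]
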