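# FASTA sequence identifiers used by NCBI: a database tag followed by one
# to three pipe-separated fields (some of which may be empty, as in
# "pir||G36364").  Format reference: NCBI C++ Toolkit documentation
# (https://ncbi.github.io/cxx-toolkit/pages/ch_demo, fasta identifiers).
datatypes:

  db_tag:
    values: ["ref", "gb", "tpg", "emb", "tpe", "dbj", "tpd", "sp", "tr",
             "pir", "pdb", "prf", "pat", "pgp", "gnl", "lcl", "bbs",
             "bbm", "gim", "gi", "gpp", "nat"]

  # one pipe-separated component: accession, locus, chain, country code,
  # serial number ... possibly empty
  id_field:
    regex: "[A-Za-z0-9_.]*"

  id_fields:
    list_of: id_field
    min_length: 1
    max_length: 3
    splitted_by: "|"

  ncbi_id:
    composed_of:
      - db_tag: db_tag
      - fields: id_fields
    splitted_by: "|"

testdata:
  db_tag:
    valid: ["ref", "gi", "nat"]
    invalid: ["xy", "REF", ""]
  ncbi_id:
    valid:
      "ref|NM_010450.1":
        db_tag: "ref"
        fields: ["NM_010450.1"]
      "gb|M73307|AGMA13GT":
        db_tag: "gb"
        fields: ["M73307", "AGMA13GT"]
      "tpg|BK003456|":
        db_tag: "tpg"
        fields: ["BK003456", ""]
      "emb|CAM43271.1|":
        db_tag: "emb"
        fields: ["CAM43271.1", ""]
      "tpe|BN000123|":
        db_tag: "tpe"
        fields: ["BN000123", ""]
      "dbj|BAC85684.1":
        db_tag: "dbj"
        fields: ["BAC85684.1"]
      "tpd|FAA00017|":
        db_tag: "tpd"
        fields: ["FAA00017", ""]
      "sp|P01013|OVAX_CHICK":
        db_tag: "sp"
        fields: ["P01013", "OVAX_CHICK"]
      "tr|Q90RT2|Q90RT2_9HIV1":
        db_tag: "tr"
        fields: ["Q90RT2", "Q90RT2_9HIV1"]
      "pir||G36364":
        db_tag: "pir"
        fields: ["", "G36364"]
      "pdb|1I4L|D":
        db_tag: "pdb"
        fields: ["1I4L", "D"]
      "prf||0806162C":
        db_tag: "prf"
        fields: ["", "0806162C"]
      "pat|US|RE33188|1":
        db_tag: "pat"
        fields: ["US", "RE33188", "1"]
      "pgp|EP|0238993|7":
        db_tag: "pgp"
        fields: ["EP", "0238993", "7"]
      "gnl|taxon|9606":
        db_tag: "gnl"
        fields: ["taxon", "9606"]
      "lcl|hnm271":
        db_tag: "lcl"
        fields: ["hnm271"]
      "bbs|316342":
        db_tag: "bbs"
        fields: ["316342"]
      "bbm|464147":
        db_tag: "bbm"
        fields: ["464147"]
      "gim|442187":
        db_tag: "gim"
        fields: ["442187"]
      "gi|21434723":
        db_tag: "gi"
        fields: ["21434723"]
      "gpp|GPC_123456789":
        db_tag: "gpp"
        fields: ["GPC_123456789"]
      "nat|AT_123456789.1|":
        db_tag: "nat"
        fields: ["AT_123456789.1", ""]
    invalid:
      - "xy|123"
      - "q|123"
      - "ref"
      - "sp|P01013|OVAX_CHICK|EXTRA|MORE"
      - "gi|21434723|x|y|z"
      - "ref|NM 010450"
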