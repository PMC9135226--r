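Package: FlatFormats
Title: Declarative Specification, Parsing and Writing of Line-Oriented Text Formats
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative specification language for line-oriented text
    formats, compiled into validating and parsing machinery. Format
    specifications are written as YAML or JSON documents describing named
    datatypes (constants, value sets, regular expressions, numeric
    intervals, lists, labeled and tagged lists, ordered compositions and
    alternatives) together with validation, formatting and transformation
    rules. Given a compiled specification, the package decodes text into
    structured values, encodes values back into text, and validates either
    side, on single strings or on files with line, unit, section and file
    scopes, including element-at-a-time streaming. Specifications can
    include other specifications (with namespaces and overrides), embed
    test data, and drive automatic generation of valid and invalid
    examples. Builtin specifications cover FASTA, FASTQ, NCBI FASTA
    sequence identifiers, sequence database accessions, a tabular
    assembly-graph subset with typed tags, and the tab-separated EGC
    (expected genomic content) rule format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, yaml, jsonlite, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'spec-model.R'
    'regex-compiler.R'
    'codec.R'
    'decode-file.R'
    'loader.R'
    'testkit.R'
    'builtin.R'
    'cli.R'
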