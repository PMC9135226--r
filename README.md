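# FlatFormats

Declarative specification, parsing and writing of line-oriented text
formats for bioinformatics.

Bioinformatics data lives in line-oriented text formats — FASTA, FASTQ,
SAM, GFA, GFF3 and a long tail of tool-specific tabular files — and for
many of them no parsing library exists, only a prose description.
FlatFormats is for anyone who would otherwise hand-write yet another
parser: a format is described *once*, in a small YAML or JSON document,
and the package compiles that description into validating and parsing
machinery.  It is aimed at R users building pipelines around such formats,
at tool authors who want to ship a machine-readable specification instead
of prose, and at anyone needing to repair files that a standard-compliant
parser rejects.

## The core idea

A specification names **datatypes**, each of one of twelve kinds:

- scalars: `constant`, `values` (a member of a set), `regex`, `regexes`,
  `integer`, `unsigned_integer` (base 2/8/10/16), `float` (open or closed
  interval bounds);
- compounds: `list_of`, `labeled_list` (`label:value`), `tagged_list`
  (`name:code:value`, the code selecting the value's datatype),
  `composed_of` (ordered fields, trailing ones optional);
- alternatives: `one_of` (first match wins).

Definitions carry formatting rules (constant prefixes/suffixes, field
delimiters), validation rules (intervals, sets, lengths, required fields)
and transformation rules (text↔value maps, e.g. `D` ↔ `"deletion"` or
`T`/`F` ↔ booleans; a designated value for the empty string).  Loading a
specification resolves includes (with namespaces and overrides), checks
the dialect syntax, rejects circular references via depth-first cycle
detection over the dependency graph, and compiles each datatype into an
anchored regular expression (or a split-based plan where an exclusive
delimiter permits).  Decoding, encoding and validation — of strings or of
files with line / unit / section / file scopes, including streaming — then
work uniformly for every described format.

Builtin specifications cover NCBI FASTA sequence identifiers, sequence
database accessions (SRA/ERA/DRA, UniProtKB, Trace Archive, INSD,
BioProject/BioSample, RefSeq, Ensembl), FASTA, FASTQ, a GFA-like
assembly-graph subset with typed tags, a SAM-like two-section subset, and
the tab-separated EGC (expected genomic content) rule format.

## Worked example

```r
library(FlatFormats)

spec <- loadBuiltinSpec("ncbi_id")
str(decode("sp|P01013|OVAX_CHICK", spec, "ncbi_id"))
#> List of 2
#>  $ db_tag: chr "sp"
#>  $ fields:List of 2
#>   ..$ : chr "P01013"
#>   ..$ : chr "OVAX_CHICK"
```

The decoded value is a plain mapping: the database tag (`sp`, SWISS-Prot)
and the pipe-separated fields (accession and entry name).  Encoding is the
inverse:

```r
encode(list(db_tag = "gb", fields = list("M73307", "AGMA13GT")),
       spec, "ncbi_id")
#> [1] "gb|M73307|AGMA13GT"
```

Files decode record by record.  `generateFixture()` writes a deterministic
example file — here three EGC records (`P` defines a phenotype group, `A`
attributes; `.` is the missing-value marker):

```r
egc <- loadBuiltinSpec("egc")
f <- tempfile()
generateFixture("egc", 3, seed = 42, path = f)
cat(readLines(f), sep = "\n")
#> P	ayj9rxg	phenotype group ayj9rxg
#> A	etzcy09	attribute etzcy09	.
#> A	et71c6x	attribute et71c6x	count_kovh

recs <- decodeFile(f, egc, "line")
str(recs[[1]]$value)
#> List of 3
#>  $ record_type: chr "P"
#>  $ id         : chr "ayj9rxg"
#>  $ description: chr "phenotype group ayj9rxg"
```

Specifications test themselves: `generateExamples()` builds valid and
invalid cases for any datatype (boundaries first, deterministic in the
seed), and `runTestdata()` executes them or the testdata embedded in the
specification file:

```r
td <- generateExamples(egc, "operator", nValid = 3, nInvalid = 2, seed = 0)
vapply(td$valid, `[[`, character(1), "text")
#> [1] "=" "<" ">"
td$invalid_encoded
#> [1] "=~X" "<~X"
runTestdata(egc)
#> TestReport: 31 passed, 0 failed
```

Command line tools (`exec/tf_decode`, `tf_encode`, `tf_validate`,
`tf_spec`) wrap the same operations for shell pipelines; validation
signals through the exit status (0 valid, 1 invalid, 2 usage error):

```sh
tf_decode string -s ncbi_id.yaml -t ncbi_id 'lcl|hnm271'
# {"db_tag":"lcl","fields":["hnm271"]}
tf_spec gentest -s egc.yaml -d record_A --seed 1 -o cases.yaml
tf_spec test -s egc.yaml -t cases.yaml
```

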