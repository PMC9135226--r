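---
title: "Declarative specification and parsing of line-oriented text formats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Declarative specification and parsing of line-oriented text formats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FlatFormats)
```

## The problem

Bioinformatics runs on line-oriented text formats — FASTA, FASTQ, SAM, GFA,
GFF3, and a long tail of tool-specific tabular formats.  Many of these are
described only in prose, and writing a parser for each one means writing
(and debugging) regular expressions and field-splitting code again and
again, once per format and once per language.  FlatFormats takes the
declarative route: a format is described once, as a small YAML or JSON
document naming its *datatypes*, and the package compiles that description
into validating and parsing machinery.  Given the compiled specification,
the same four operations are available for any format:

* `decode()` — text representation to structured value,
* `encode()` — structured value to text representation,
* `isValidEncoded()` / `isValidDecoded()` — validation of either side,
* `decodeFile()` — the same, over files, with line / unit / section /
  file scopes and streaming.

Because the parsing machinery is generated from regular expressions, the
formats that can be described are (essentially) regular languages.  That
covers most line-oriented bioinformatics formats; it excludes formats with
unbounded nesting such as Newick trees, which are out of scope by design.

## The specification dialect

A specification document has up to four sections: `datatypes`, `testdata`,
`include` and `namespace`.  A datatype definition is a mapping with exactly
one *kind* key; twelve kinds exist, in three families:

| family | kind | accepted texts |
|---|---|---|
| scalar, discrete | `constant` | one fixed text |
| | `values` | a member of an ordered set |
| scalar, pattern | `regex` | one regular expression |
| | `regexes` | any of an ordered list of expressions |
| scalar, numeric | `integer` | signed base-10 integer in a closed interval |
| | `unsigned_integer` | unsigned integer, base 2/8/10/16, in an interval |
| | `float` | floating point number in an open or closed interval |
| compound | `list_of` | homogeneous delimited list with length bounds |
| | `labeled_list` | `label:value` elements, labels from a set |
| | `tagged_list` | `name:code:value` elements, code selects the value type |
| | `composed_of` | ordered fields, trailing ones optionally absent |
| either | `one_of` | alternatives, first match wins |

Sibling keys attach rules: formatting (`prefix`, `suffix`, `splitted_by` /
`separator`, `internal_separator`), validation (`length`, `min_length`,
`max_length`, `required`, `n_required`, `must_match`) and transformation
(`decoded`, a text-to-value map; `empty`, the value represented by the
empty string; `canonical`, the text form emitted when several are valid).
Two shorthands keep specifications concise: a bare scalar string is a
`constant`, and a plain list is a `values` definition.  In a
sub-definition position a bare string names another datatype; `@name`
forces a reference anywhere.

```{r}
spec <- loadSpecification("
datatypes:
  strand: {values: ['+', '-'], decoded: {'+': 'forward', '-': 'reverse'}}
  interval:
    composed_of:
      - start: {integer: {min: 0}}
      - end: {integer: {min: 0}}
      - strand: strand
    n_required: 2
    splitted_by: ':'
")
decode("10:250:-", spec, "interval")
encode(list(start = 10, end = 250), spec, "interval")
```

Defaults were chosen once for the whole dialect: the element delimiter
defaults to a tab (the dominant convention in the formats this package
ships), the internal separator of labeled and tagged lists to `:`, float
bounds are closed unless `min_excluded`/`max_excluded` opens them, integer
intervals are always closed, all `composed_of` fields are required unless
`n_required` says otherwise, and lists require at least one element unless
`min_length: 0`.  For base-16/8/2 unsigned integers, decoding accepts an
optional `0x`/`0o`/`0b` prefix; canonical encoding omits it unless the
`prefix` flag is set.

### Includes, namespaces, overrides

Specifications compose: the `include` section imports datatypes from other
files, recursively.  An included file's `namespace` prefixes its exported
names (`gfa::tag`), with internal references rewritten accordingly; a
whitelist imports single datatypes (plus their transitive dependencies, so
references always resolve); an `override` tree replaces or extends any
sub-component of an imported definition, addressed by its key path.
Overriding is what makes *repairing* invalid files cheap: import the
official specification, widen exactly the broken element, decode with the
patched spec, re-encode with the original:

```{r}
orig <- loadBuiltinSpec("gfa_like")
patched <- loadSpecification(sprintf("
include:
  - path: '%s'
    override:
      tags:
        tagged_list:
          z: {regex: '[ !-~]*'}
", builtinSpecPath("gfa_like")))
bad <- "S\tseg1\tACGT\tab:z:hello world"
isValidEncoded(bad, orig, "segment_line")
v <- decode(bad, patched, "segment_line")
encode(v, orig, "segment_line")
```

### Compilation

Loading resolves includes, validates the dialect syntax (diagnostics carry
the path into the tree and the keys valid at that context), builds the
dependency graph of datatype references, rejects cycles by depth-first
search (reporting one witness cycle), and compiles an anchored regular
expression per datatype.  Where a compound datatype declares an *exclusive*
delimiter (`splitted_by`), parsing splits on the literal delimiter; where
the delimiter may also occur inside fields (`separator`), parsing uses the
pattern with backtracking.  Numeric interval membership, required-label
sets and duplicate checks are enforced post-match rather than expanded into
the pattern (interval-to-regex expansion explodes; the checks are part of
validation anyway), so for those datatypes the pattern accepts a lexical
superset and full validation decodes.  `saveCompiled()` writes the resolved
table as a versioned JSON archive; `loadCompiled()` re-derives the matchers
from the stored definitions, which keeps the archive engine-independent,
and archives are accepted anywhere a specification path is.

## Decoded values and round trips

Decoded values use plain R types: `NULL` (missing), logical, numeric,
character, unnamed lists (sequences) and named lists (mappings).  Two
round-trip guarantees are tested across all builtin specifications:

* **value round trip** — `decode(encode(v))` equals `v` exactly (integers
  exact; floats are formatted with the shortest representation that reads
  back equal);
* **text round trip** — `encode(decode(t))` re-decodes to the same value.
  The re-encoded *text* may legitimately differ from `t` when several
  representations exist: non-injective `decoded` maps emit the canonical
  (first-listed) text, `0xff` re-encodes as `FF`, and a tagged-list value
  re-encodes with the first type code able to represent it (so a
  single-character string stored as `Z` re-encodes as `A`, and an integral
  float as `i`).  These are deliberate canonicalization choices, not
  information loss: the decoded values are equal.

## File scopes and streaming

`decodeFile()` applies a datatype to a file according to its *scope*: one
record per line (`line`), per fixed group of lines (`unit`, e.g. FASTQ's
4-line records — a file whose line count is not a multiple of the unit
size is an error, strictness being the safer default), per maximal run of
matching lines (`section`), or one record for the whole file (`file`).
File scope expects a `composed_of` whose fields are `list_of` sections
over line datatypes; sections are consumed by maximal munch, in order, and
a required section that cannot be satisfied raises a structural error with
the offending line number — this is how "header must precede alignments"
is enforced.  With `streaming = TRUE` the same structural validation runs,
but records are emitted one line at a time (labelled with their section),
so arbitrarily large files can be processed in bounded memory; streaming
and whole-file decoding are tested to agree record-for-record.

## Testing specifications

A specification can embed (or accompany) a `testdata` section: valid
text-to-value pairs, invalid texts, invalid values.  `runTestdata()`
asserts decode results, re-encode round trips and rejections, and
aggregates a report.  `generateExamples()` produces such test data
automatically: valid examples constructively per kind (interval boundaries
first, then interior points; every member of a value set; recursive
composition for compounds; pattern-directed synthesis for regex kinds,
with repetition capped at three so examples stay humanly readable) and
invalid examples by boundary violation, member mutation, separator
corruption and prefix removal — each verified against the validator before
being emitted, and all of it deterministic in the seed.  A datatype that
accepts every string has no invalid examples; asking for some is an error
rather than a silent empty answer.  The synthesizer understands the
pattern subset used throughout the builtin specifications (literals,
classes, ranges, negation, `.`, escapes, groups, alternation, the usual
quantifiers); lookarounds and backreferences are rejected.

## Builtin specifications and the fixture generator

The package ships seven specifications under
`inst/extdata/specs/`: NCBI FASTA sequence identifiers (`ncbi_id`, all 22
database tags with their documented examples embedded as testdata),
sequence database accessions (`accessions`: INSD read archives, UniProtKB,
Trace Archive, INSD assembled sequences and metadata, RefSeq, Ensembl —
grammars encoded from the databases' public documentation, cited in the
file), the EGC expected-genomic-content rule format (`egc`), FASTA and
FASTQ (`fasta`, `fastq`), a GFA-like assembly-graph subset (`gfa_like`)
and a SAM-like two-section subset (`sam_like`).  The EGC schema fixes
per-record positional fields (A: id, name, computation; T: id, taxon name,
rank; P: id, description; E: subject, attribute, operator, value)
consistent with the format's structural rules — '#' comments, tab
separation, a single-letter record type, `.` as the missing marker,
exactly four record types; the field semantics beyond those rules are
illustrative.  The GFA-like and SAM-like specifications are deliberately
representative subsets (sections, tags) rather than full-fidelity copies
of the upstream formats.

`generateFixture()` writes deterministic, fully decodable files in these
formats and reports its own record tally, which tests compare against
decode results.  What the generator emulates is structure — record-type
mixtures, comments, FASTQ quality strings of matching length, segments
before the links that reference them.  What it does not emulate is
real-world mess: encoding anomalies, truncated final records,
cross-record inconsistencies (FASTQ sequence/quality length equality and
GFA reference integrity are cross-record constraints and deliberately a
caller-side concern).  Passing tests therefore demonstrate the machinery,
not the cleanliness of any particular archive's files.

## Numerical and degenerate-input choices

* Integers decode exactly (R integer where it fits, double beyond, exact
  up to 2^53); leading zeros and a leading `+` are accepted on input and
  never emitted.
* Floats decode to binary doubles; encoding emits the shortest decimal
  that reads back equal.
* Newlines: reading uses universal newline handling and tolerates a
  missing final newline; encoding emits `\n`.
* Input is treated as UTF-8 text.
* An empty file is zero records under line scope; the empty *string* is a
  valid representation only where a definition says so (`min_length: 0`,
  an `empty` rule, or zero required fields).
* Decode errors report the failing sub-definition path and the character
  offset of the first position where no continuation could match; file
  decoding adds the line number.
* `one_of` is deterministic: first matching alternative on decode, first
  representable alternative on encode.
* Patterns are capped at 500 capturing groups per datatype with a clear
  error; compound definitions parse hierarchically (outer structure first,
  elements recursively), so nesting does not multiply group counts.

## Problem sizes used in the checks

The shipped test-and-acceptance machinery exercises: 100 generated valid
examples per builtin datatype for the round-trip suite; exhaustive
enumeration of all 156 strings of length ≤ 3 over a 5-symbol alphabet
against independent character-level recognizers for five scalar datatypes;
50 random dependency graphs of up to 8 nodes against a transitive-closure
oracle; a 1000-record generated EGC file and a 200-alignment SAM-like file
for streaming equivalence; at least 1000 decode comparisons between
source-loaded and precompiled specifications; and generator self-tests
over seeds 0–4 for every builtin datatype.  These sizes were chosen as the
point where the checks stabilize — enlarging them changes nothing but the
runtime.

## Known limitations

* Only (essentially) regular formats are describable; embedded JSON
  delegation is an open extension point, not implemented.
* The dialect is self-contained and Table-complete but not guaranteed
  byte-compatible with other declarative format-description languages'
  files.
* Cross-record validation (identifier uniqueness, coordinate ranges) is a
  caller-side layer by design.
* Non-exclusive-separator list parsing is leftmost-greedy per element;
  pathological grammars whose correct parse requires global lookahead
  across elements may be rejected.  Exclusive delimiters avoid this
  entirely and are the recommended style.
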