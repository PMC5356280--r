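---
title: "Parsing NMR-STAR losslessly: grammar, model and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsing NMR-STAR losslessly: grammar, model and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrstar)
```

## Why a dedicated parser

BMRB entries are STAR-dialect flat files. The format is simple at a glance —
`data_<id>`, saveframes, tag–value pairs, loops — but its quoting rules are
where general-purpose tooling fails. Three constructions in particular occur
in real deposited entries and defeat regex-based readers:

1. multiline (semicolon-delimited) text containing interior semicolons;
2. a multiline block whose closing `;` sits at end-of-file with no trailing
   newline;
3. a multiline block whose closing `;` is immediately followed by the next
   token, typically `loop_`.

This package treats the grammar, not byte patterns, as the contract, and
treats *losslessness* as the defining requirement: anything parsed must
write back out (to NMR-STAR or JSON) such that re-parsing gives a
structurally identical object.

## The token grammar

`tokenize()` classifies whitespace-delimited units: `data_<id>` /
`save_<name>` / bare `save_` / `loop_` / `stop_` keywords (matched
case-insensitively, always written lowercase), `_tags`, `#` comments (only
at the start of a whitespace-delimited position), quoted values, and
multiline blocks. Decisions that needed fixing where the format leaves
room:

* **Multiline content rule.** The value is everything between the opening
  `;` and the closing column-1 `;`, excluding the newline immediately before
  the closing delimiter, and stripping one leading newline when the opening
  `;` ends its line. Thus `";\ntext\n;"` decodes to `"text"`, and the writer
  always emits `"\n;\n<value>\n;\n"` so values that themselves begin with a
  newline survive the round trip. This convention is canonical for this
  package.
* **Null placeholders.** `.` and `?` are ordinary VALUE tokens preserved
  verbatim — converting them to `NA` would make the round trip lossy, and
  downstream semantics (missing vs unknown) belong to the consumer.
* **Framecodes.** `$name` references stay literal VALUE tokens, `$`
  included.
* **Encoding.** Input is decoded as UTF-8; undecodable bytes are replaced
  with a warning rather than aborting, because legacy entries occasionally
  contain stray bytes. CRLF is normalized to LF before column-1 detection.
* **One unrepresentable case.** A *value* containing a line that begins with
  `;` cannot be written in STAR at all: inside a multiline block a column-1
  semicolon always terminates the block. `format_value()` refuses such
  values explicitly instead of producing text that re-parses differently.
  This is a limitation of the format, not of the implementation.

## The ordered model

Entries are ordered named lists: the reserved key `"data"` first, then
saveframes, with loops under `loop_0`, `loop_1`, … and (optionally) captured
comments under `comment_0`, …. A loop is a pair: the field-tag sequence and
the record list, every record keyed exactly by the fields in order. All
scalars are strings; the only numeric interpretation in the package happens
in the chemical-shift viewer, and even there values are validated, not
converted.

Structural equality (`structurally_equal()`) — identical key sequences at
every level and identical value strings, provenance excluded — is the
round-trip contract. Byte-identical output is deliberately *not* promised:
the writer uses one fixed layout (one tag–value per line, indented loop
fields, one record per row), because preserving input whitespace would
require carrying formatting state through the model for no analytical
benefit.

Policy decisions in the parser:

* a duplicate tag in one saveframe is an error in strict mode (default) and
  keep-first-with-warning in lenient mode — silent overwrite would be an
  invisible data loss;
* a value with no preceding tag is an error in strict mode rather than being
  skipped, so corrupt files surface instead of parsing "successfully";
* a loop terminated by `save_` instead of `stop_` (seen in historical
  depositions) is accepted only in lenient mode, with a warning;
* a file with several `data_` blocks yields the first block and a warning —
  BMRB distributes one block per file, and silently concatenating blocks
  would invent structure;
* comments encountered inside a loop body attach to the enclosing
  saveframe's comment slots, since a loop is a pure (fields, records) pair.

## JSON mapping

`to_json_star()` maps the model one-to-one: saveframes to objects, each loop
to the two-element array `[fields, records]`, every scalar a JSON string,
member order significant. The reader requires order preservation, which
`jsonlite` provides when simplification is disabled; an alternative JSON
backend would be acceptable only under the same guarantee. Output is
compact UTF-8 by default (JSON is already several-fold more verbose than
NMR-STAR); `pretty = TRUE` indents by 4 for human reading. On bulk
conversion `.str` ↔ `.json` extensions are swapped; unknown extensions keep
their stem and gain the target extension.

## Sources and streaming

`read_star_entries()` accepts files, directories (recursive, lexicographic
order, hidden and non-text files skipped unless a pattern is given), zip and
tar(.gz/.bz2) archives, `http(s)://`/`file://` URLs, and all-digit BMRB
accession ids; precedence when a string is ambiguous is existing path > URL
scheme > accession id. Ids are turned into URLs through configurable
templates (`options(nmrstar.bmrb_url_template_3_1 = ...)`), because endpoint
URLs change faster than software; the test suite exercises the mechanism
exclusively through `file://` templates and never touches the network. The
version-specific template must be chosen by the caller — an accession id
alone does not determine which format version a server returns.

The stream is pull-based: resolving a source builds name/reader pairs
without I/O, and each `next_entry()` call reads and parses exactly one
document, so a corpus of any size needs one document in memory at a time.
Archive members are extracted one at a time to a temporary file and removed
after reading — the memory contract is per-document, and the instrumented
counter (`stream$state$docs_read`) lets tests verify that consuming *k*
entries reads exactly *k* documents.

## Chemical-shift extraction

Assigned shifts are located by **loop field schema**, not by saveframe
category tags: a loop containing `_Atom_chem_shift.Seq_ID` / `.Comp_ID` /
`.Atom_ID` / `.Val` is a version 3.1 shift loop, one containing
`_Residue_seq_code` / `_Residue_label` / `_Atom_name` / `_Chem_shift_value`
is version 2.1. Category tags differ across versions and are mislabeled in
some legacy files, whereas the loop schema is what actually carries the
data. Each matching saveframe becomes one chain (labeled by saveframe
name); residues are ordered by sequence position; ambiguity-code and error
columns are ignored for viewing. Shift values remain strings for display
fidelity and are only checked (with a warning) for numeric parseability.
The DOT tree has exactly `1 + chains + residues + atoms` labeled nodes —
a closed count the tests verify — and image rendering uses the external
Graphviz `dot` engine when present, otherwise the DOT text itself is
written with a warning so no information is lost.

## The fixture generator and what it shows

All verification runs on synthetic fixtures emitted with their own ground
truth: the generator returns the raw document text *and* the exact entry
object a correct parse must produce, plus counts, key order and loop shapes.
Writing document text directly (rather than through the package's writer)
lets fixtures exercise surface syntax a well-behaved writer never emits —
the three multiline edge constructions above, keyword-lookalike values,
values with embedded `#`/`$`/quotes, empty loops, comments. Values are
drawn from pools chosen to force every branch of the writer's quoting
policy. Same seed, same bytes: generation saves and restores the session
RNG state.

Shift fixtures draw a chain/residue/atom composition with plausible ppm
ranges (backbone amides near 8/118 ppm, CA near 55, side-chain carbons in
the 20–35 range) and can emit it in both tag schemas with identically named
saveframes, which is what makes cross-version extraction comparable
end-to-end. Problem sizes used by the verification suite and
`scripts/acceptance.R` — 1,000-file corpora for structural properties,
10,000 randomized documents for lexer/automaton agreement, 40-member
archives per compression format, 30 cross-version shift pairs — were chosen
so every property is exercised hundreds of times while the whole suite runs
in minutes on one CPU.

What passing these tests does **not** show: the fixtures do not mimic the
tag vocabulary, saveframe ordering conventions or sheer size of real BMRB
depositions (real 3.1 entries reach tens of megabytes with dozens of
saveframe categories), and no schema/dictionary validation against the
official NMR-STAR dictionary is attempted — a file can be grammatically
perfect and semantically wrong. The package's claims are about the grammar
and losslessness, which is exactly what the fixture corpus measures.

## Verification strategy

Two independent implementations of the lexical grammar are compared: the
production line/regex lexer and a deliberately naive single-pass character
automaton (`tokenize_reference()`), which also counts character touches to
certify the single-pass property (≤ 3 per character including lookahead).
Structural properties (parse/manifest agreement, both round trips, key-order
preservation, loop value conservation) are checked over seeded random
corpora rather than hand-picked examples. The equality predicate itself is
property-tested as an equivalence relation, so the round-trip checks cannot
silently weaken.

## Known limitations

* Only the first `data_` block of a multi-block file is read.
* No CIF/mmCIF dialect support (bracket lists, triple quotes) — the lexer is
  NMR-STAR-specific by design.
* No recovery of partial structure from files that fail to parse.
* Loop tables are not column-aligned on output.
* Values containing a line-initial semicolon cannot be represented (format
  limitation, refused explicitly).
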