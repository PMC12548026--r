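---
title: "Auditing SOFT metadata: models, parameters and design choices"
author: "softaudit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing SOFT metadata: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softaudit)
```

# The problem

Bacterial transcriptomic samples deposited in GEO-style repositories are
described by SOFT records: line-oriented plain text in which `^` lines open
an entity (sample, series, platform), `!` lines carry `field = value`
attributes, and `#`-prefixed plus delimited rows carry a data table.
Whether those samples can be reused at scale depends on (i) how much of
the metadata is machine-readable, (ii) whether the biological context in
the free-ish `characteristics` field is structured enough to tabulate, and
(iii) whether the raw measurements can still be recovered and
renormalized. `softaudit` turns each of those questions into a computable
statistic on any SOFT corpus.

# SOFT parsing model

Attribute lines are split at the **first** `=` only; values may contain
further `=` characters (protocols and genotypes often do). Entity
prefixes (`Sample_`, `Series_`, `Platform_`) are stripped and the
remainder lower-cased to obtain canonical cross-entity field names, while
the original spelling is retained so that `write_soft()` is lossless:
`parse → write → parse` is an identity on the parsed representation, a
property the test suite checks on every generated corpus. Undocumented
fields are preserved and flagged, never rejected — their existence is a
finding, not an error. Dates follow the SOFT `Mon DD YYYY` convention; an
unparseable date yields `NA` with a warning and the record is excluded
from growth series. SOFT does not document multi-line attribute values;
repeated attribute lines are treated as a multimap, which covers the
observed usage (`supplementary_file_1`, repeated `characteristics_ch1`).

# Field catalog accounting

The bundled reference catalog has 52 rows: the 45 canonical metadata
fields observed in bacterial microarray/RNA-seq SOFT records (32
documented, 13 only observed in community usage), plus seven
documented-only extras that exist purely to reconstruct the official
documentation's arithmetic — three SAGE-specific fields (`anchor`,
`tag_count`, `tag_length`), three table delimiters (`table_begin`,
`table`, `table_end`) and one duplicated `geo_accession`. That yields
39 documented names → 38 nonredundant → 32 metadata fields proper, and
45 = 32 + 13 dataset fields of which 24 are biological or technical.

The machine-readable share counts `structured` rows among the 45; the
single `semi_structured` field (`characteristics`) is folded into the
unstructured side, because only that convention reconciles the catalog
(34/45 = 75.6% structured) with a ~75% / ~25% split. Both the exact and
the nearest-5% rounded shares are reported. Matching is case-insensitive
on canonical names, since SOFT capitalization varies by entity prefix.

# Characteristics structuredness

A characteristics string is parsed by splitting at the first `": "`
(colon + space), falling back to the first `:`. The two-stage policy
minimizes false splits inside URLs (`source: http://x.org/a`) and clock
times while honoring the `<tag>:<value>` convention; it is implemented in
one place (`parse_characteristics()`) and tested against a brute-force
earliest-valid-split oracle. A *word* is a maximal run of non-whitespace
characters — the simplest definition consistent with counting words, and
one that represents the extreme tags observed in real corpora (up to 86
words on microarray, 12 on RNA-seq).

A GSM is **empty** when it has no non-whitespace characteristics content
(missing and whitespace-only are deliberately not distinguished: both
mean "no information"); **putative structured** at stringency `k` when
*all* of its pairs parse and have tag and value word counts ≤ `k`; and
**not structured** otherwise. One malformed pair therefore taints the
whole sample — the point of the definition is tabulability, and a table
row cannot be half-parsed. `k = Inf` is the explicit "any number of
words" sentinel. The sweep uses a joint limit (`k_tag = k_value = k`) by
default, matching the one-axis presentation of stringency curves;
independent limits are supported.

The GSM × tag table canonicalizes tags (case-fold, collapse internal
whitespace) but never values. A duplicate tag within one GSM keeps the
first value and warns — the upstream convention is silent, and keep-first
is order-stable and auditable via the collision count. "Strain-like" tag
matching (token `strain` at word boundaries after punctuation stripping)
is a declared package policy, not an upstream rule; `constraint` does not
match, `strain/background` does.

# Reusability triage

Rules fire in a fixed order and the fired rule is recorded per GSM.
Decisions where the upstream description is ambiguous, resolved here as
package policy:

- *Unknown* distribution class is **not** treated as noncommercial; the
  unrecoverable rule names noncommercial explicitly, so unknowns fall
  through to the later rules.
- "Only having a nonprocessable supplementary file type" is read
  literally as *all* files nonprocessable; mixed file sets survive.
- `.tif` and `.jpeg` are folded into the `.tiff`/`.jpg` nonprocessable
  classes; compression suffixes (`.gz`, `.bz2`) are stripped before the
  extension is read.
- A GSM whose files mismatch its platform's standard extension (e.g. an
  Affymetrix platform with only `.txt`) is potentially reusable, not
  reusable — extension/manufacturer pairing is required for the reusable
  class.

Manufacturer names are normalized through a bundled alias table
(`Affymetrix, Inc.`, `AFFX`, `Roche NimbleGen`, ...); every alias maps to
exactly one canonical name, checked exhaustively in the tests.

# Taxonomy

Live taxonomy services are out of scope by design: lineage is a pluggable
TSV (organism → superkingdom/phylum/species) with a bundled fixture
covering the commonly deposited bacterial model organisms, two archaea,
two eukaryotes and a phage. More than one distinct organism annotation
yields `multiple_organism`; the ambiguous repository annotations are
matched by case-insensitive substrings (`synthetic`/`chimeric`,
`environmental sample`) — the upstream vocabulary beyond those examples
is not published, so the pattern list is a package policy and is
configurable in source.

# Growth models

Cumulative yearly submission counts are fitted to a logistic
$y = L/(1+e^{-k(x-x_0)})$ (saturating technology) by nonlinear least
squares and to a cubic polynomial (still-accelerating technology) by OLS.
Numerical choices:

- **Centered coordinates everywhere.** Raw-year cubic coefficients around
  $x \approx 2000$ suffer catastrophic cancellation (the $x^3$ term is
  ~8·10^9), so fitting uses $x - \bar x$ and raw-basis coefficients are
  derived outputs only. For the same reason the package never validates a
  projection against low-precision printed raw-basis cubic coefficients.
- **Logistic initialization** $L_0 = 1.05\,\max y$, $x_{0,0} =
  \mathrm{median}(x)$, $k_0 = 0.5$, bounded $L, k > 0$, `port`
  algorithm, tolerance 1e-10; noiseless self-generated series are
  recovered to better than 1e-6 relative error (tested), and with
  Gaussian noise at 1% of $L$ the median over 100 replicates recovers $L$
  within 5% and $x_0$ within 0.5 year.
- Degenerate inputs fail loudly: < 4 points, constant series,
  rank-deficient designs and non-convergence raise errors with
  diagnostics rather than returning garbage; `k = 0` makes the inflection
  undefined.
- The asymptote is the closed-form limit of the model value; the
  inflection equals $x_0$ analytically, and a numeric second-derivative
  root-finder agrees to 1e-6 in the tests.

Yearly binning of calendar submission dates is the default granularity;
fractional years are supported in evaluation so mid-year endpoints can be
modeled.

# The synthetic world

`corpus_config()` defaults encode one fixed "stated world" (they are not
tuning knobs): a 48/52 microarray/RNA-seq split; putative-structured
shares of 0.70 (microarray) and 0.95 (RNA-seq) at unbounded word counts
and 0.10 at the single-word stringency for both; per-sample word-count
maxima of 86 and 12; microarray records spanning 2000–2025 with
logistic-shaped cumulative growth ($k = 0.3968$, $x_0 = 2011.245$) and
RNA-seq 2009–2025 with an increasing cubic; a microarray triage
composition of 44% reusable and 17% with no supplementary file (the two
anchored proportions), with the remaining unrecoverable causes (no
manufacturer 2%, all-nonprocessable 1.5%, noncommercial 1.5%) and the
34% potentially-reusable remainder chosen as a realistic decomposition;
manufacturer shares 23/21/11% Affymetrix/Agilent/NimbleGen among
reusable-class platforms; and an organism mix dominated by *E. coli*,
*B. subtilis*, *M. tuberculosis*, *P. aeruginosa* and *S. aureus* with
2% multiple-organism and small synthetic/environmental/unclassified
slices. Empty-characteristics rates (12% microarray, 1% RNA-seq) reflect
that missing characteristics are essentially a microarray-era phenomenon;
no published point value exists, so these were fixed once at values a
curator would call plausible.

The generator records every intended label (structuredness class and
word limit, triage label and rule, taxon label, submission year) in a
manifest *at generation time*, so tests compare audit output against
ground truth that never flows through the audit code. Randomness is
drawn from per-GSM, per-aspect substreams derived by hashing (seed, GSM
index, aspect), so changing the file mix provably cannot perturb
characteristics sampling (tested).

What the generator does **not** emulate: real tag vocabulary diversity
(a handful of tags versus thousands), semantic noise in values, units,
two-channel samples, monthly submission granularity, series-level
structure beyond a trivial grouping, and supplementary file *contents*.
A green test therefore establishes that the pipeline measures what the
generator encoded — exact label recovery on noiseless settings, binomial
agreement on sampled mixes — not that any particular live-repository
percentage is correct. Repository-wide percentages require crawling the
live repository and are deliberately out of scope.

# Known limitations

- The reference catalog is a snapshot; repositories add fields, and
  auto-discovery of current submission vocabularies is a non-goal.
- The 64 raw observed field names of the audited dataset are not itemized
  publicly; the 64 → 45 reduction is exercised on synthetic corpora where
  the raw-name ground truth is known.
- Triage trusts file extensions ("the file extension is informative about
  its content"); no file contents are downloaded or parsed.
- `strain`-likeness and the special taxon patterns are heuristics by
  necessity; both are single functions with declared policies, easy to
  swap.
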