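---
title: "Merging multi-informant pedigrees: model, algorithms and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging multi-informant pedigrees: model, algorithms and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedunite)
```

## The problem

Family-based genetic studies of large families rarely obtain the pedigree
from a single authoritative source. Several relatives (informants) each
report the part of the family they know: overlapping, incomplete, sometimes
contradictory sub-pedigrees, with patchy disease status, phenotype and
genotype data. Building the study pedigree means *unifying* these reports —
deciding which structure to keep, eliminating people reported twice,
resolving discordant attribute values, and remembering where every value
came from so it can later be traced back to its source material.

`pedunite` implements that unification as a scriptable library plus a batch
command-line tool: an in-memory pedigree model, three merge algorithms,
field-level provenance, individual-level comparison/reconciliation, and a
simulator that produces exactly this multi-informant situation for testing.

## The pedigree model

A pedigree is an ordered collection of individuals, one per row of a
tab-delimited file: an identifier, father and mother references, a sex, and
an ordered set of named attribute columns (affection status, phenotypes,
genotypes). Conventions follow LINKAGE/PED practice: the literal `"0"` is
the missing-parent (and default missing-value) sentinel, and sex is coded
`1`/`2`/`0` on file for male/female/unknown.

The family graph is whatever the parent references imply. Multiple descent
trees, multiple spouses and consanguineous marriage loops are all legal —
real extended pedigrees contain them — so `ped_validate()` flags only true
structural damage: duplicate ids, dangling parent references, individuals
referenced as father/mother with the contradicting recorded sex, and
*ancestor cycles* (someone being their own ancestor). Exactly one missing
parent is reported as a warning, not an error. Validation returns findings
rather than raising, so a damaged file can be loaded, inspected and
repaired.

### Sublineages

Every merge operates on a *sublineage*: a chosen root individual plus all
of its descendants, with no generation limit. The descendants alone do not
form a usable pedigree fragment — a copied child must not be left with a
dangling parent reference — so the sublineage's member set additionally
includes the married-in partners of descent members. The root's own parents
are never included. Whether spouses of descendants belong to a sublineage
is a genuinely open modelling question; we include exactly the co-parents
needed to complete parental pairs, and all membership counts in reports and
tests are stated over descent plus these required partners.

Traversal order is deterministic everywhere (breadth-first by generation,
file order within a generation, partners inserted at first encounter), so
two runs produce byte-identical output files that can be diffed.

## The three merge algorithms

A merge has a direction — from a *source* pedigree into a *destination* —
and is anchored by one individual in each.

* **Replacement** (`merge_replace`): the destination branch rooted at the
  anchor is removed and the source sublineage takes its place; the source
  root inherits the anchor's parent references, occupying the same position
  in the family. Married-in partners of removed members are dropped only if
  nothing ties them to the result any more (no surviving children, no
  surviving parents); a partner with other children must survive.
* **Combination** (`merge_combine`): the source sublineage is folded into
  the destination. Individuals present in both are represented once; the
  others are appended with parent references remapped through the duplicate
  pairing. The output can serve as the destination of another combination,
  so informant views can be folded in one at a time.
* **Addition** (`merge_add`): the whole source sublineage is appended, its
  root becoming a new sibling of the anchor (it receives the anchor's
  parents — which is why the anchor may not be a founder).

In all three modes, duplicated individuals appear exactly once in the
result. When a duplicated pair disagrees on a field where both sides have a
value, **destination precedence** applies: the destination's value is kept,
the source's discarded, and the conflict is recorded in the merge report.
Because of this asymmetry the recommended workflow is to review
discordances with `compare_individual()` and resolve them explicitly with
`reconcile_individual()` *before* merging.

Two behaviours around duplicates are deliberate design choices rather than
forced by the problem statement:

* **Gap-fill.** Destination precedence only governs *discordant* values.
  When the destination's value is the missing sentinel and the source has
  one, discarding the source value would destroy information, so the source
  value fills the gap; every fill is flagged in the report and its
  provenance is set to the source's label, keeping the asymmetry auditable.
  The rule is symmetric in outcome: whichever side holds the only value,
  that value wins.
* **Identity is never guessed.** Duplicates are matched on an exact key —
  by default the identifier, optionally a composite key such as
  `c("id", "BIRTHYEAR")`. One individual matching two candidates is an
  error listing them. An incoming id that exists in the destination without
  matching as a duplicate is a collision: an error by default, or an
  explicit recorded rename (`on_collision = "rename"`), never silent
  aliasing.

Every merge is pure: inputs are untouched and a fresh pedigree, provenance
table and report are returned. Merge results are re-validated before being
returned; a merge that would produce structural damage (e.g. two informants
disagreeing about a shared parent's sex) fails loudly instead.

## Field-level provenance

The provenance table maps every (individual, field) pair — father, mother,
sex and each attribute column — to exactly one source label, typically a
pedigree file name or `"manual"`. It stores the *current* source only, not
an audit history: the goal is that any value in the unified pedigree can be
traced back to its original source material, not a timestamped log (that is
an explicit non-goal).

On disk the table is the metadata file of the configuration/pedigree/
metadata trio: a TSV with the same geometry as the pedigree file — one row
per individual in the same order, one column per pedigree column — whose
first cell repeats the individual's id and whose remaining cells hold the
labels. The printed description of the format pins down only this
row-correspondence; mirroring the file geometry with the id in the name
column's slot is the minimal faithful reading, and is what makes geometry
mismatches mechanically detectable. When no metadata file accompanies a
pedigree, a default table is created with the pedigree file's name as the
source of every field.

All operations preserve *totality*: after any sequence of edits and merges
through the public API, the provenance domain equals the pedigree's
(id, field) grid, with no gaps and no orphans.

## Files and formats

A dataset is a trio: a configuration file (line-oriented
`KEY whitespace VALUE`, `#` comments; unknown keys are treated as
appearance options, stored verbatim and re-emitted byte-identically, never
interpreted), the tab-delimited pedigree file, and the optional metadata
file. Pedigree files carry a header row by default — self-describing files
survive column drift — with a headerless mode driven by the configuration's
column list. Reads accept CRLF and pad short rows with the missing
sentinel; writes are UTF-8, LF, and deterministic, making serialization a
byte-level fixed point (`write ∘ read ∘ write = write`).

Non-destructiveness is enforced mechanically: any file read during the
session is registered, and writers refuse to overwrite it unless asked to
edit in place (`in_place = TRUE` / `--in-place`).

Two exports target downstream tools: pre-makeped **LINKAGE PED** (family,
individual, father, mother, sex, then chosen attribute columns, `0` for
missing; ids with whitespace must be re-coded to integers, with the
id-to-integer map written alongside so the export is invertible), and
**Graphviz DOT** for visualization — one node per individual (box/ellipse/
diamond by sex), one point node per parental pair, edges parent → marriage
→ child. Rendering engines and image formats are out of scope; DOT is the
hand-off. Note one consequence of the data model: childless couples do not
exist in PED-style data (partnership is only implied by co-parenthood), so
a "couple" without children is drawn as two unconnected nodes.

## The simulator

`generate_pedigree()` grows a family forward from a founder couple: each
couple has a Poisson number of children (`mean_children`, default 2.2 — a
multi-child mean keeps branches wide enough to split among informants);
each reproducing child either marries in a new partner or, with probability
`partner_prob` (default 0.15), another lineage member of the same
generation, producing the marriage loops real extended pedigrees contain.
Partners enter the pedigree only when the couple has children, mirroring
PED-style data where partnership is implied by co-parenthood. Default depth
is 4 generations — deep enough for multi-generation sublineages while
keeping desk-scale sizes. The default attribute schema carries an affection
status, a binned quantitative phenotype and a single-marker genotype with
missing rates of 0.05/0.25/0.2, reflecting that verbal family history
yields patchy clinical and genetic data.

`make_informant_views()` turns one ground truth into informant reports.
Each view is anchored (by default at the head of the largest lineage, so
views overlap at the top and can be recombined there); a member at
undirected kinship distance $d$ from the anchor is retained with
probability $(1-\omega)^{\max(0, d-1)}$, where $\omega$ is the omission
rate (default 0.25) — informants always know their immediate relatives and
grow hazier outward. Parents of retained members are repaired back in, so
every ancestor chain is intact and every view validates; spouses whose
children were all forgotten are dropped, since an informant does not report
the spouse of a relative they forgot. Retained non-missing attribute values
are mis-reported with probability `discordance_rate` (default 0.1),
replaced by a different value of the column's observed domain; role fields
are never perturbed. Every omission and perturbation is listed in the
view's manifest, so tests can predict comparison and merge outcomes
exactly.

What the simulator does *not* emulate — and hence what passing tests do not
show about real data: misspelled or inconsistently formatted names (no
fuzzy identity), informants who misremember *structure* (wrong parents,
swapped generations), genotype transmission (attribute values are
i.i.d. per person, not Mendelian), and realistic demography. Synthetic
results demonstrate the algebra of merging, not record-linkage robustness.

## Numerical and degenerate-input choices

* Missing sentinel `"0"`, LINKAGE sex codes; chosen once for
  interoperability with downstream analysis programs.
* Cycle detection uses the boolean transitive closure of the child→parent
  relation; at desk scale (tens to a few hundred members) the dense-matrix
  fixpoint is simplest and exact.
* Empty pedigrees, childless roots, founder anchors (legal for replacement,
  an error for addition), header-only files, and padding of short rows are
  all defined rather than accidental.
* Ties and orderings are fixed everywhere (file order, generation-major
  traversal) so results are reproducible byte-for-byte.
* Seeds: the simulator consumes its `seed` via `set.seed` internally, so
  fixtures are fully specified by their spec objects.

## Scale used by the shipped tests

The test suite and the reproduction script run entirely on synthetic
fixtures at desk scale: families of roughly 10–150 members, 3–5
generations; 500 randomized merge plans for the count identities; ~1000
(pedigree, individual) cases of ≤30 members for the brute-force traversal
oracles. These sizes exercise every code path (loops, multi-spouse,
renames, pruning) while the whole suite stays in the tens of seconds.

## Known limitations

* Identity resolution is exact-key only; no probabilistic record linkage.
* Provenance keeps the latest source, not a history; there is no undo.
* Kinship coefficients, Mendelian-error checking and id-agnostic graph
  isomorphism are out of scope.
* Reconciliation writes into one explicitly chosen target pedigree; the
  other input is never modified.
* The GUI-style side-by-side display is reduced to the textual
  `format_field_diff()` report and the DOT export.
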