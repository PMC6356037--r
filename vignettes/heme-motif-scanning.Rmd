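---
title: "Scanning protein sequences for transient heme-binding motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning protein sequences for transient heme-binding motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemescan)
```

## The problem

Heme (iron-protoporphyrin IX) is best known as a permanently bound
prosthetic group, but it also acts as a signaling molecule by binding
proteins *transiently*. Such regulatory binding happens at short,
surface-exposed sequence stretches — heme-binding motifs (HBMs), or
heme-regulatory motifs (HRMs) when a functional consequence is known — in
which a Cys, His or Tyr side chain coordinates the heme iron. A transient
interaction requires fast association and dissociation, so the dissociation
constants involved are moderate (high nanomolar to low micromolar) and the
determinants are local: the coordinating residue and its immediate
sequence neighborhood.

`hemescan` operationalizes this picture. Its scanner treats every Cys, His
and Tyr as a candidate axial ligand (position P⁰) and evaluates the
nonapeptide window X₄(C/H/Y)⁰X₄ around it — the same 9-mer geometry used in
the combinatorial-library experiments that motivated the motif classes. The
goal is triage: a ranked, annotated list of candidate sites that a user can
take to spectroscopy, not a binding-affinity predictor.

## The motif model

For each window the scanner computes:

* **Net charge**: (#K + #R) − (#D + #E). His is counted neutral at the
  implied physiological pH and no terminal charges are applied, because the
  window is an internal protein fragment, not a free peptide. The
  experimental observation being encoded is qualitative — negatively
  charged nonapeptides tend not to bind heme, positively charged ones bind
  with comparably high affinity — so an integer counting convention is the
  simplest reproducible choice, and it is what the report's charge comments
  are based on.
* **CP dipeptide**: Cys at P⁰ immediately followed by Pro. The proline
  constrains the backbone and CP motifs behave as a class of their own
  (penta-coordinated, regardless of further coordination sites).
* **Ancillary sites**: additional C/H/Y residues at offsets −4…+4 (≠ 0).
  Coordination partners farther away than the window cannot participate in
  the 9-mer complex geometry the classes describe, so the definition is
  deliberately restricted to the window.

Windows within four residues of a terminus are truncated and flagged rather
than dropped: nothing in the underlying experiments invalidates terminal
motifs, and silently hiding sites would be the worse failure mode.

### The eight classes

```{r}
hbm_classes()
```

The class space is the partition (axial ligand) × (ancillary present), with
cysteine split further by CP: I/II (Cys without CP), III/IV (CP), V/VI
(His), VII/VIII (Tyr), where the even-positioned member of each pair
carries an ancillary site. `coordination` and `topology` record what
peptide-level NMR and spectroscopy found for representatives of each class
— penta-coordination for III, IV, V and VII, hexa for I, II, VI and VIII,
with sandwich-like complexes for I/VIII and loop/clamp-like complexes for
II/VI — and are attached to reports as *hints*, never as predictions about
a particular protein. Two readings were genuinely open here: the V–VIII
numbering follows the penta/hexa grouping above, and class IV is recorded
with "single" topology (CP motifs stay penta-coordinated whether or not an
ancillary site is present, and no loop has been described for them). Both
choices are metadata only; re-mapping the table changes no scan result.
A window with several ancillary sites, of any mixture of ligand types, is
treated the same as one with a single ancillary site: the classification
criterion is binary.

The classic class II exemplar is HXXXC — a distal His at offset −4, i.e. a
three-residue spacer, which is the geometry needed to fold a loop/clamp
onto the heme:

```{r}
w <- extract_window(protein_record("demo", "HAAACAAAA"), 5)
w
assign_class(w)
annotate_window(w)
```

## Exposure filtering: two operating modes

A buried coordination site is a false positive for *transient* binding. In
**default mode** the scanner therefore keeps only sites labeled exposed.
The original pipeline delegates this to the WESA meta-predictor (an
ensemble of five machine-learning methods); re-implementing WESA is
explicitly out of scope here, so the package offers one interface with two
interchangeable providers:

* `read_accessibility_file()` imports per-residue labels or RSA fractions
  (binarized at `rsa_cutoff`, default 0.25 — the common surface/buried
  convention) produced by any external predictor or by DSSP on a structure;
* `builtin_predictor()` is a deliberately simple stand-in: mean
  Kyte–Doolittle hydropathy over a sliding window (default width 9), with
  means above 0 — the scale's hydrophobic/hydrophilic midpoint — labeled
  buried. Norleucine (`J`) is scored with leucine's value, being its
  straight-chain isomer; codes with no defined hydropathy (X, B, Z, U, O)
  contribute 0 with a warning.

Sites with *unknown* exposure pass the filter, with a warning: missing
evidence should not suppress a candidate. **Structure mode** skips
filtering entirely; the user curates against the known structure.

The hydropathy heuristic is not a validated accessibility predictor and is
not tuned to match WESA; it exists so that default mode works out of the
box and so that a real predictor can be plugged in through the same
`accessibility_profile` interface without code changes.

## Consensus-pattern screening

Screening a proteome with consensus sequences was originally done through
the ScanProsite web service. `parse_pattern()`/`match_pattern()` implement
the same pattern dialect locally: fixed residues, `[..]` alternatives,
`{..}` exclusions, `x` wildcards with `(n)`/`(n,m)` repeats, `<`/`>`
anchors, elements joined by `-`. Semantics worth knowing:

* at each start position the *shortest* expansion of ranged repeats is
  reported (deterministic; users wanting all expansions can iterate fixed
  repeats);
* overlapping matches at distinct starts are all reported;
* an `X` in the *sequence* satisfies only wildcards — an unknown residue is
  never taken as evidence for a specific requirement.

```{r}
match_pattern("[HY]-x(3)-C", protein_record("t", "AHAAACA"))
```

## The spectroscopic rule engine

Band positions in the underlying studies are approximate ("~"), so each
rule uses an explicit, user-settable tolerance
(`spectro_tolerances()`): Soret 370 ± 8 nm for the penta band and
415–435 nm for the 420–430 nm band; ν₃ 1491/1505 ± 5 cm⁻¹; g ~6 and ~2
± 0.4 with the low-spin range 1.5–3. The rules themselves:

| technique | observation | verdict |
|---|---|---|
| UV/Vis | lone Soret maximum ~370 nm | penta |
| UV/Vis | lone maximum 420–430 nm | ambiguous (not uniquely assignable) |
| UV/Vis | maxima in both bands | mixed |
| rRaman | ν₃ ~1491 cm⁻¹ | penta — with the caveat that free hemin gives the same band |
| rRaman | ν₃ ~1505 cm⁻¹ | hexa |
| rRaman | double band | mixed |
| cwEPR | g ~6 and g ~2 (high-spin) | penta |
| cwEPR | three g-values within 1.5–3 (low-spin) | hexa |

`combine_evidence()` passes unanimous verdicts through, lets any decisive
technique resolve an ambiguous UV call, and flags a penta/hexa conflict
between techniques as `mixed` with a conflict entry in the evidence table.
Widening a tolerance can only turn `undetermined` into a match, never flip
penta into hexa, and the combined verdict is invariant to the order in
which techniques are supplied. The UV-group label (I: ~370 only, II:
420–430 only, III: both, IV: neither) deserves a caveat: the four spectra
groups are named but not defined in the underlying work, so this mapping is
an interpretation and is labeled as such wherever it is printed. The ν₇
band is accepted as input but contributes no rule — no quantitative mapping
for it is available — and the engine never does spin-multiplicity
arithmetic; spin states are stored as strings inside rule text only.

```{r}
coordination_call(soret_maxima_nm = c(370, 425), nu3_wavenumbers_cm1 = 1491)
```

## The library simulator and what it does (not) emulate

`generate_library()` reproduces the *sequence design* of the combinatorial
screen: nonapeptides X₄(C/H/Y)⁰X₄ whose flanks are drawn i.i.d. from the
19-letter alphabet of all standard residues minus Cys (disulfide avoidance)
and Met (reserved by the elimination chemistry) plus norleucine (`J`). Two
center-weight regimes matter and are easy to confuse:

* the *synthesized* library is uniform over C/H/Y centers;
* the observed *hits* show H ~40%, Y ~40%, C ~20%.

The default `library_spec()` uses the hit frequencies, because the
simulator's main job is generating sequence sets whose summary statistics
can be checked against the reported hit statistics; uniform weights are one
argument away. Under uniform flank sampling the fraction of peptides with
at least one additional His/Tyr has the closed form 1 − (17/19)⁸ ≈ 0.589,
consistent with the reported ">50% of hits carry ancillary sites"; the
Monte-Carlo estimate at n = 10,000 falls within three binomial standard
errors of it (both checked in the test suite at n = 10,000, a size chosen
so that 3 SE ≈ 1.2 percentage points resolves the 20% figure comfortably).

What the simulator does **not** model: bead-based screening chemistry, the
heme-concentration series, binding outcomes, or any flank-composition bias
of real hits (a polar-residue enrichment was observed but never quantified,
so flanks stay uniform; tests passing on simulated libraries therefore say
nothing about enrichment effects in real screens). Draws are seeded
(`spec$seed`) and the generator restores the caller's RNG state, so fixture
generation is reproducible and non-invasive.

## Numerical and interface conventions

* Positions are 1-based in all user-facing output; offsets inside windows
  are signed, relative to P⁰.
* Selenocysteine (U) is *not* a coordination site; Met/Lys — rare ligands —
  can be enabled with the `scan_met_lys` config switch and are then
  reported as `unclassified`.
* FASTA parsing accepts lowercase (uppercased) and trailing `*` (stripped
  with a warning); any character outside the accepted alphabet is rejected
  at parse time with record, position and character. How non-standard codes
  should be treated is not prescribed anywhere in the source material; this
  alphabet policy is the package's own.
* Reports are tab-separated with a fixed column order and input row order,
  so identical inputs yield byte-identical files.
* The report's `comment` column joins comments with `"; "`; an empty
  comment list prints as an empty field, never `NULL`.

## Known limitations

* The exposure heuristic is a hydropathy proxy, not a solvent-accessibility
  predictor; in default mode its labels gate the output, so users with any
  real accessibility source should prefer `--accessibility`.
* Binding affinity is not predicted — the net-charge comments are
  qualitative, and experimental K_D ranges cannot be computed from
  sequence.
* The classes describe 9-mer-local geometry; coordination partners outside
  the window (e.g. in tertiary contacts) are invisible to the scanner.
* PROSITE *profile* (matrix) patterns and the live PROSITE database are out
  of scope; patterns are user-supplied text.
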