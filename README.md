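# hemescan

Transient ("regulatory") heme binding — as opposed to the permanent burial of
heme as a prosthetic group — is mediated by short, surface-exposed sequence
motifs built around a coordinating cysteine, histidine or tyrosine side
chain. `hemescan` is an R package and command-line tool for anyone who wants
to triage a protein sequence for such candidate heme-binding motifs (HBMs)
before committing to wet-lab binding studies.

## What it computes

For every Cys/His/Tyr in a protein sequence (the putative axial ligand at
position P⁰), the scanner extracts the nonapeptide window
**X₄(C/H/Y)⁰X₄** (truncated at the termini), and reports:

* the **net charge** of the window, counted as (#K + #R) − (#D + #E) with
  His neutral and no terminal charges — a negative net charge disfavors and
  a positive net charge favors heme binding;
* whether the ligand forms a **CP dipeptide** (Cys at P⁰ immediately
  followed by Pro), the best-characterized heme-regulatory element;
* **ancillary coordination sites** — further C/H/Y residues inside the
  window, reported as signed offsets from P⁰ (e.g. the HXXXC motif has a
  distal His at −4, three spacer residues away from the central Cys);
* the **HBM class**, one of eight: the axial ligand (C/H/Y) crossed with
  presence/absence of an ancillary site, with cysteine split further by the
  CP dipeptide. Classes III, IV, V and VII are expected penta-coordinated;
  I, II, VI and VIII hexa-coordinated, with sandwich-like (I, VIII) or
  loop/clamp-like (II, VI) complex topology attached as a hint.

In the **default mode**, candidate sites are filtered to surface-exposed
residues — via a user-supplied per-residue accessibility file (e.g. from
WESA or DSSP) or a built-in Kyte–Doolittle sliding-window heuristic. The
**structure mode** reports every site and leaves curation to the user.

Companion modules provide:

* a local **PROSITE-syntax pattern matcher** (`C-x(2,4)-{P}`,
  `[HY]-x(3)-C`, `<`/`>` anchors) for consensus-sequence screening;
* a **spectroscopic rule engine** mapping UV/Vis Soret maxima (~370 nm
  penta; 420–430 nm not uniquely assignable; both → mixture),
  resonance-Raman ν₃ bands (~1491 cm⁻¹ penta, ~1505 cm⁻¹ hexa, double band
  mixed) and cwEPR g-values (g ~6 + g ~2 high-spin penta; three g-values in
  1.5–3 low-spin hexa) to a coordination-state call;
* a seeded **combinatorial-library simulator** of the X₄(C/H/Y)⁰X₄
  nonapeptide design (19-letter flank alphabet: the standard residues minus
  Cys/Met plus norleucine `J`).

## Worked example

```r
library(hemescan)
report <- run_scan(">toy\nHAAACAAAARKCP\n", mode = "structure")
write_report(report, stdout())
```

```
record_id  position  axial_ligand  motif      net_charge  class  exposure  comment
toy        1         H             HAAAC      0           VI     unknown   additional coordination site(s): C at +4; class VI: expect hexa-coordination (loop topology)
toy        5         C             HAAACAAAA  0           II     unknown   additional coordination site(s): H at -4; class II: expect hexa-coordination (loop topology)
toy        12        C             AARKCP     2           III    unknown   CP motif; positive net charge: heme binding favored; class III: expect penta-coordination (single topology)
```

Row 2 is the classic HXXXC motif: the central Cys at position 5 with a
distal His at offset −4 (a three-residue spacer) — class II, expected to
form a hexa-coordinated loop/clamp-like complex. Row 3 is a CP motif with a
favorable net charge of +2, expected penta-coordinated.

A coordination-state call from spectroscopy:

```r
coordination_call(soret_maxima_nm = 425, epr_g_values = c(1.8, 2.2, 2.9))
#> <coordination_call> verdict: hexa (UV-group II, an interpretive label)
#>   cwEPR    hexa      three g-values within ~1.5-3 (low-spin): hexa-coordinated complex
#>   UV/Vis   ambiguous Soret maximum in 420-430 nm band: not uniquely assignable to one coordination state
```

The same functionality is available from a shell via the installed script
(`system.file("exec/hemescan", package = "hemescan")`), with subcommands
`scan`, `patterns`, `spectro`, `simulate` and `classes`.

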