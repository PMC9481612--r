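---
title: "Methods: particle re-centering and crosslink-based model validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: particle re-centering and crosslink-based model validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryolink)
```

`cryolink` packages two procedures for cryo-EM of flexible multi-subunit
assemblies: segmented re-centering of particle coordinates from 2D class
averages, and structural validation of a model by crosslinking mass
spectrometry (CLMS). This vignette records the underlying models, the
tunable parameters and their defaults, the design choices made where the
design was genuinely open, what the synthetic-data generators do and do
not emulate, and the package's known limitations.

## Particle re-centering

### Model

During 2D classification, each particle image is aligned to its class
average by an in-plane translation (`origin_x`, `origin_y`, pixels) and an
in-plane rotation `psi` (degrees). Coordinates live in the micrograph
pixel frame with the origin at top-left, x right and y down (the image
raster convention used by extraction software); `psi` is the rotation
taking the particle to the class frame. A region of interest at offset
(dx, dy) from the class-average center therefore sits in the micrograph
at

$$x_\mathrm{new} = x - o_x + dx\cos(\psi \pi/180) + dy\sin(\psi \pi/180)$$
$$y_\mathrm{new} = y - o_y + dy\cos(\psi \pi/180) - dx\sin(\psi \pi/180)$$

i.e. the offset is rotated back through `psi` (a length-preserving map:
two offsets always end up the same distance apart as they started) and
added to the origin-corrected coordinate. The sign structure above —
$+dy\sin$ in x, $-dx\sin$ in y — is the contract; it corresponds to
rotating the class-frame offset by $-\psi$ under the y-down raster
convention, and the test suite pins it against an independent 2×2
rotation-matrix oracle.

### Design choices

* **Offsets come from a file, not a click.** Interactive selection on a
  displayed class average is just a way of producing (dx, dy); the
  library consumes a declarative offsets file (`class_id, dx, dy[,
  label]`), which separates UI from arithmetic and makes the step
  reproducible.
* **Alignment is consumed.** Output particles get `origin = 0` and
  `psi = 0`: re-extraction at the new coordinates starts a fresh
  alignment, and retaining stale origins would double-apply the
  translation on the next refinement round.
* **Out-of-bounds particles are dropped, not clamped.** When a micrograph
  extent and new box size are given, a particle whose new box
  `[x_new − box/2, x_new + box/2)` leaves the micrograph is removed and
  counted; clamping would silently shift region centers. The report's
  counts always satisfy `n_input = n_written + n_dropped + n_skipped`.
* **Fractional coordinates are written as-is**; rounding to integer
  pixels is left to the extraction program, avoiding a rounding rule the
  downstream software may not share.
* **Binned class averages** are handled by a scale factor (default 1)
  multiplying the offsets; classification is often run on downsampled
  images and the offset is recorded in those pixels.
* **Two STAR dialects.** Legacy single-table files keep origins in
  pixels; optics-grouped files keep them in Ångström
  (`rlnOriginXAngst/YAngst`) and are converted to pixels on read using
  the optics-block pixel size, so the transform always works in one
  unit. The source dialect is restored on write. Column matching is
  exact on the canonical tags — fuzzy aliases could silently mis-map an
  alignment column and corrupt the geometry. Unknown columns are carried
  through verbatim.

### What the particle generator emulates

`gen_star()` plants a true region center per particle, draws `psi`
uniform on [−180, 180), origins Gaussian (default sd 5 px, a typical
alignment shift at ~1.4 Å/px pixel sizes), and synthesizes the
coordinate by the *analytic inverse* of the transform, so the recenter
module under test and the generator share no code. It emulates metadata
only: there are no particle images, no noise model, no classification
errors, and every particle's psi/origin is exactly consistent with its
class. Passing the recovery test (1000 particles, max error < 1e−6 px)
therefore demonstrates the coordinate arithmetic, not robustness to
misalignment — on real data the accuracy of re-centering is bounded by
the accuracy of the 2D alignment itself.

## Crosslink validation

### Model

An MS-cleavable NHS-ester crosslinker (DSSO) covalently links residues
whose side chains are close in space — primarily lysines, with
Ser/Thr/Tyr and protein N-termini as secondary targets. A search engine
identifies crosslinked peptide pairs with scores, q-values and
target/decoy flags. Validation against a structural model proceeds:

1. **Site mapping**: the crosslinked residue is
   `peptide_start + marked_pos − 1`, verified against the protein
   sequence when available.
2. **Deduplication**: records are redundant when they link the same
   unordered residue-level pair (protein, site); the highest-scoring
   record is kept, ties broken by first appearance. The residue-level
   key (rather than the peptide pair) is used because different tryptic
   peptides covering the same linked residues are repeated evidence for
   one crosslink.
3. **FDR**: pair-level `FDR = (TD − DD)/TT`. A negative raw value
   (DD > TD) is clamped to 0 in the reported estimate — an FDR is a
   proportion — with the raw value retained for diagnostics. q-values
   are consumed from the upstream search, never recomputed, and the
   cutoff (default 0.01) is a strict "below". The FDR can be computed
   before and after deduplication; both are of interest since redundant
   high-scoring targets deflate the post-dedup estimate.
4. **Distance measurement**: Euclidean Cα–Cα distance from PDB/mmCIF
   coordinates, author residue numbering (crosslink tables use
   UniProt-aligned numbering; mmCIF `label_seq_id` is ignored). With
   multiple chain copies per subunit the minimum over cross-copy pairs
   is taken: a crosslink is explained if *any* copy pair satisfies it.
   Alternate locations resolve to the highest-occupancy conformer, ties
   to the first listed. Only Cα atoms are consulted.
5. **Classification** with thresholds in `validation_config()`:

   | parameter | default | meaning |
   |---|---|---|
   | `satisfied_max` | 30 Å | classification cutoff |
   | `reference_observed_max` | 23 Å | empirical DSSO bound, reported only |
   | `theoretical_range` | 26–30 Å | theoretical DSS reach, reported only |
   | `unresolved_proximity_max` | 50 Å | plausibility bound for one-sided gaps |

   The 30 Å cutoff is the conventional black/gray drawing boundary for
   crosslinks on a model and the theoretical upper reach of DSS; on the
   packaged table the violated set is identical under a 23 Å or 30 Å
   cutoff (the three violations measure 51.8, 57.4 and 314.3 Å), so the
   choice does not affect the headline counts. A distance exactly at the
   cutoff counts as satisfied — "< 30" vs "> 30" leaves equality
   unassigned, and the permissive reading is taken and documented here.
6. **Unresolved crosslinks** (a linked residue absent from the model,
   as in disordered termini) get a proximity estimate: the distance from
   the resolved side's Cα to the nearest modeled Cα flanking the gap on
   the missing side, minimized over both flanks and all chain copies,
   flagged plausible at ≤ 50 Å. The flank-anchor rule is this package's
   reconstruction — the underlying claim is only that a small flank
   distance keeps the missing residue in the linker's neighbourhood,
   since the true distance exceeds the flank distance by at most the
   disordered segment's contour reach. Both sides missing yields
   "estimate unavailable" rather than an error.

### The packaged crosslink table

`table1_fixture()` returns a transcription of the 33 published
intersubunit DSSO crosslinks of the human augmin octamer, with printed
model distances on 28 rows and missing-peptide flags on 5. Two
transcription subtleties are recorded in the CSV header: one row's
bold-residue marker was lost in text extraction and is restored from
sibling rows carrying the same peptide, and the running text's rounded
distances for three crosslinks differ slightly from the printed table
values (the table values are carried). The peptide superscripts are read
as peptide *start* residues — the reading consistent across repeated
peptides — with `superscript = "site"` providing the alternate
interpretation in which the superscript marks the crosslinked residue
itself. In distance-supplied mode (`assess_crosslinks(...,
distances = )`) the printed distances exercise classification without
the deposited model; `recheck_published_distances()` recomputes them
when the user supplies PDB 7SQK locally with a chain mapping (the
deposition does not state the subunit-to-chain assignment in text, so
the mapping is user input).

### What the toy structure generator emulates

`gen_toy_structure()` builds Cα-only chains as straight rods (default
rise 3.8 Å/residue, the Cα spacing of an extended chain), deletes
residue ranges to emulate disordered regions, and translates chains so
that each planted crosslink achieves its target distance exactly (to
1e−3 Å after the 3-decimal PDB serialization). It emulates none of the
real geometry of helical-bundle assemblies — no secondary structure, no
sterics, no B-factors — and cannot realize arbitrary systems of distance
constraints (a second constraint between two already-placed chains
errors unless it is already satisfied). It exists to give the distance
engine and the unresolved-proximity estimator a ground truth computed by
direct vector arithmetic, independent of the lookup path under test.

## Numerical choices and degenerate inputs

* STAR floats are written with six decimal places (≥ 6 significant
  digits at micrograph scale), giving read–write–read agreement to
  better than 1e−6 px; psi periodicity (`psi` vs `psi + 360`) holds to
  1e−9 px.
* Empty inputs are valid everywhere: an empty particle set writes a
  header-only STAR, an empty offsets file skips every particle, an
  empty crosslink table assesses to an empty report.
* `compute_fdr` with `TT = 0` is an error (undefined estimate), not a
  silent 0.
* Duplicate class offsets and chains mapped to two subunits are
  configuration errors, caught at parse time.
* Assessments are deterministic; regenerated reports are byte-identical
  except for their timestamp.

## Problem sizes

The test suite and the reproduction script run at desk scale: 1000
synthetic particles for recovery (with 100-case property sweeps for
isometry and periodicity), decoy sets of ~100–260 records, toy
structures of 2–3 chains × 20–60 residues, and the 33-row packaged
table. These sizes exercise every code path; the arithmetic is
vectorized and scales linearly in particles and crosslinks, so
million-particle STAR files are limited only by memory for the parsed
table.

## Limitations

* Metadata only: no MRC/TIFF image I/O; re-extraction, classification
  and refinement belong to the upstream cryo-EM packages.
* No spectrum-level CLMS search and no decoy database generation; the
  package post-processes search-engine output.
* Straight-line Cα–Cα distances only — no solvent-accessible surface
  distance pathfinding, which can matter for residues whose direct line
  crosses the protein core.
* The re-centering equations are implemented with the printed sign
  structure; whether that corresponds to an active or passive rotation
  under a particular RELION version's psi convention is not re-derived
  here. Users applying the transform with offsets produced by other
  display tools should verify orientation on a known case (the packaged
  forward simulator provides one).
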