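# becdyn

Biphasic, emergent, and coexistent (BEC) dynamics of signed regulatory
circuits, built around TNF-induced cell death.

## The problem

TNF can kill a cell by apoptosis (through caspase-8, C8) or by necroptosis
(through phosphorylated RIP3, pRIP3). The upstream kinase RIP1 regulates
both arms non-monotonically: partial RIP1 knockdown *enhances* RIP3
phosphorylation, complete knockout abolishes it. Three signatures define
this regime:

* **BD (biphasic)** — steady-state pRIP3 rises then falls along the RIP1
  expression axis; the relative peak-to-end drop
  `(peak − end)/peak ≥ 1%`.
* **ED (emergent)** — the rise is abrupt: the readout climbs by ≥ 50% of
  its pool within a 10% dose increment (window slope ≥ 5).
* **CD (coexistent)** — at intermediate RIP1, apoptotic (high C8) and
  necroptotic (high pRIP3) attractors coexist.

The scale of biphasic dynamics is `H = (pRIP3_peak − pRIP3_at_100%RIP1) /
RIP3_total`. The structural requirement for BD+ED is an **incoherent
feedforward loop** (IFFL): RIP1 → RIP3 directly, and RIP1 → C8 ⊣ RIP3
indirectly; the RIP3 → RIP1 positive feedback adds coexistence.

`becdyn` provides, for whoever models small signaling circuits:

* a compiled ODE engine for signed Hill-kinetics circuits
  (`dx/dt = Σ k (T − x) φ(a) − Σ k x φ(a) − d x`, `φ(a) = aⁿ/(aⁿ + jⁿ)`),
  with steady-state detection, multistart attractor search, and
  dose–response generation under expression scaling;
* the five-component death-circuit model (TRADD, RIP1, RIP3, and two
  caspase-8 activation routes) with labeled interaction terms k1–k9,
  knockouts, expression scans, and the k5–k7 phase plane of H;
* BD/ED/CD classifiers, regulation typing, piecewise four-parameter
  logistic fits of H;
* Langevin simulation, trajectory-density potential landscapes
  (`U = −ln ρ`), basin counting, and dwell-time Shannon entropy of the
  death-mode decision;
* Latin hypercube random-parameter screening and exhaustive two-/three-node
  topology-to-function mapping with IFFL detection and a layered atlas.

## Worked example

```r
library(becdyn)
model <- necroptosis_model()            # shipped synthetic reference set
curve <- rip3_dose_curve(model, seq(0, 1, length.out = 101))

classify_biphasic(curve)$flag           # TRUE  (peak-to-end drop >= 1%)
round(classify_emergent(curve)$max_slope, 1)
round(compute_H(curve), 2)

co <- classify_coexistent(model$circuit, "RIP1",
                          seq(0.04, 0.16, by = 0.01),
                          n_starts = 60, seed = 2)
range(co$interval)                      # RIP1 window with two attractors
```

On the shipped reference parameterization this prints `TRUE`, an
emergence slope of `7.5` (the pRIP3 pool climbs ~75% of its total per 10%
RIP1 near the emergence point), `H = 0.55`, and a coexistence window of
`0.04–0.09` of wild-type RIP1: the biphasic, emergent, and coexistent
signatures in one screenful. Removing the IFFL terms reproduces their
necessity:

```r
scan <- term_knockout_scan(model)
scan$term[!scan$BD]
#> [1] "k5" "k7" "k9"
```

The reference parameter file
(`inst/extdata/necroptosis_reference_synthetic.yaml`) is *synthetic*: it
was calibrated against published behavior of this circuit (see the
methods vignette), not transcribed from fitted kinetics.

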