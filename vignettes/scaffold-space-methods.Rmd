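---
title: "Methods: pharmacophore-aware scaffolds and implicit chemical space"
author: "ScaffoldSpace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacophore-aware scaffolds and implicit chemical space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
procedures, the parameters that matter, the numerical choices, and what
the synthetic data can and cannot tell you about real screening output.

## The scaffold model

A *primary scaffold* is defined against a 3D pose and a pharmacophore
hypothesis, not against the 2D structure alone: it is the smallest
retrosynthetic fragment of the posed molecule that

1. carries at least one attachment point (a cut was made somewhere),
2. contains at least one ring, and
3. contains every atom that realizes a *key* pharmacophore point of the
   matched hypothesis.

This is deliberately stricter than a Bemis–Murcko framework: two molecules
with the same ring system but different interacting substituents get
different primary scaffolds, because the substituent that satisfies a key
point is part of what makes the scaffold privileged for the target.

Fragmentation follows the published BRICS scheme — sixteen chemical
environments and their compatibility matrix — implemented here as
transparent atom predicates on the package's molecular-graph substrate.
Only acyclic bonds are ever cut, so ring systems are never opened. Two
properties of that choice do real work:

* Cutting **all** cleavable bonds splits the molecule into elementary
  pieces whose quotient graph is a forest. Every fragment obtainable by
  cutting any subset of at most `maxCuts` bonds corresponds to a connected
  subtree whose boundary has at most `maxCuts` edges, so
  `bricsFragments()` enumerates subtrees instead of the exponentially
  larger family of cut subsets. The test suite checks this equivalence
  against a brute-force cut-subset oracle, and checks the cleavable-bond
  set itself against an independent reference implementation.
* Keeping *all* subtrees — not only the leaves — is what "retrosynthetic
  intermediates" means operationally: a scaffold may sit at any partial
  level of decomposition. The default `maxCuts = 6` is a tractability cap;
  molecules needing more simultaneous cuts to liberate a fragment are rare
  at screening-compound sizes.

"Contains every key-point atom" is the coverage reading of "matching all
key pharmacophore points" for a 2D fragment of a 3D pose: the fragment, in
the parent's pose, must include the atoms whose features matched the key
points. Without re-embedding the fragment in 3D — which would introduce a
conformer generator and its noise — atom coverage is the only well-defined
criterion, and it is exact at the resolution the match report provides.

Ties for "smallest" (fewest heavy atoms, attachment points excluded) break
to the lexicographically smallest canonical SMILES, so extraction is fully
deterministic. Port labels on the extracted scaffold are semantic, not
positional: the cut whose lost periphery classified *left* (hydrophobic
side) becomes port 1, *right* becomes port 2, a third cut port 3; when two
peripheries fall on the same side, the one nearer the hydrophobic point
takes the lower label.

## Pharmacophore matching

Feature perception is a small, documented predicate catalogue (donors:
N/O with hydrogen; acceptors: N/O with an available lone pair, excluding
amide nitrogens and aromatic N–H; hydrophobes: maximal groups of carbons
without N/O/P neighbors plus thioether S and C-bound halogens; aromatic
rings by smallest-ring perception; charges excluding zwitterionic motifs).
Platforms that do industrial pharmacophore scoring have richer perception;
the point of a transparent default is that every match is auditable, and
the definition set is an ordinary R list a user can override per call.

Matching is geometric: a point matches if some feature of the same type
has its centroid within the point's radius (boundary inclusive; centroid =
unweighted mean of member-atom coordinates, in Å). The *best* feature is
the nearest one, ties broken by lowest atom index. Distances are compared
against user radii only — there are no hidden tolerances. Radii are
mandatory inputs with no default claimed faithful to any published
configuration: tolerance radii are binding-site decisions, not package
decisions. The fixture hypothesis uses 1.0 Å because its poses place atoms
exactly at the centers.

Two invariants are asserted by the tests rather than assumed: matching is
invariant under a joint rigid motion of pose and hypothesis, and enlarging
a radius can only add matches, never remove them.

## Peripheral fragments and the implicit library

Excising the scaffold atoms leaves connected peripheral pieces, each
capped with one attachment point at its severed bond. A piece attached to
the scaffold through two bonds (a fused periphery) violates the
one-port-per-fragment contract and is excluded with a warning rather than
silently mangled. Sides are classified by centroid distances in the parent
pose: nearer the hydrophobic key point → left, else right, with exact ties
going right for determinism.

The enumeration engine treats (scaffolds × left × right) as an implicit
space. Counting is pure integer arithmetic carried as decimal digit
strings, because realistic spaces exceed 64-bit integers and a count that
silently overflows is worse than none; the numeric view is exact below
2^53. Enumeration streams in lexicographic (scaffold, left, right) order
at constant memory; junctions that would violate valence are skipped and
counted, never fatal — a combinatorial space legitimately contains
incompatible pairs, and the audit trail must say how many. Sampling draws
per scaffold, without replacement, from a generator seeded by
(seed, scaffold index), so a run is reproducible and individual scaffolds
can be resampled independently. Products are not globally deduplicated
during streaming (that would break the memory contract); deduplication is
a post-pass concern.

## Reward shaping

CRV (constant reward value) gives every structure that passed all filters
exactly the configured constant — by construction the reward variance of
an accepted batch is zero, which removes the incentive for a generator to
concentrate on one high-scoring cluster. SPAG (similarity penalty to
already generated) subtracts `penaltyWeight × s_max` from the base reward,
where `s_max` is the candidate's maximum fingerprint similarity to the
archive of previously generated structures, clamped at zero; the candidate
then joins the archive. The linear-clamped form is the simplest functional
realization of "penalize similarity to what you already made"; it is a
pluggable strategy, not a claim about any platform's internal formula.
SPAG here applies after CRV capping (penalizing the capped value), an
ordering assumption the configuration documents. The default similarity is
Tanimoto over OpenBabel FP2 path fingerprints — the standard fingerprint
available in this stack; circular fingerprints would serve equally and can
be plugged in through the same interface.

The toy generator exists to make the effect of these modes observable at
desk scale, not to model any production generator: it mutates parents
(element substitution, substituent addition, terminal deletion), filters
through the structural alerts, scores under the configured mode, and
accepts structures with nonzero reward, selecting parents with probability
proportional to reward. The "default" scorer used in the demonstration is
similarity to a fixed target chemotype *zeroed below a threshold* (0.3 by
default in the paired comparison): the threshold models the pass/fail
gates of a screening reward stack, and it is what makes the default mode
genuinely exploitative — only the target's cluster survives. Under CRV the
same loop explores every seed chemotype at equal reward, and SPAG
additionally devalues what the archive already holds. The paired
comparison (10 seeded pairs, 150 iterations, 8 seed chemotypes) asserts
the *direction* — more unique primary scaffolds under CRV+SPAG — by a sign
test at α = 0.05 plus a strict mean comparison. Only the direction is a
claim; the magnitude depends on every knob of the toy loop and is not
calibrated to any published effect size.

## Filtering and descriptors

The minimal/moderate/covalent alert tiers ship as editable
`rule_id <TAB> SMARTS <TAB> description` files assembled from public
structural-alert collections. They are **not** any platform's proprietary
rule sets; the file format and the containment contract (every minimal
rule appears in moderate, enforced at load) are the stable interface, the
contents are starting points. Verdicts canonicalize before matching so
kekulization variants cannot disagree, and filtering an already-filtered
stream is a no-op. The `covalent` tier is applied like the others, with an
`invert` flag for workflows that *select* warheads instead of excluding
them. Descriptor annotation is deliberately thin (MW from standard atomic
weights including implicit hydrogens; HBA/HBD by the same definitions the
pharmacophore module uses, so the two can never disagree); synthetic
accessibility and other model-based scores are out of scope and belong
behind the plug-in hook.

## Statistics

A screened random sample of size *n* with *k* survivors gives the point
estimate `100·k/n` percent for the library-wide virtual hit rate. The 95%
interval is the Wilson score interval (via `prop.test` without continuity
correction) rather than the Wald interval, because screening hit rates are
routinely small and Wald collapses there; the tests check the closed form,
the complement identity `rate(k,n) + rate(n−k,n) = 100`, monotone
narrowing in *n*, and empirical coverage in seeded binomial simulation.
Values are stored unrounded; display rounding (tables mix 1 and 2 decimal
places) is a formatting flag.

## What the synthetic data does and does not show

`makeToyLibrary()` builds poses by joining a known scaffold with known
left/right fragments and *constructing* coordinates: the scaffold's
designated donor, acceptor and hydrophobic-group atoms are pinned to the
hypothesis centers, the left fragment is parked toward the hydrophobic
point, the right toward the polar points, everything else on neutral
circles, plus optional Gaussian noise (`noiseSd`, Å). The geometry is
chemically meaningless on purpose — downstream logic consumes coordinates
only through distance tests, so feature-level placement is the entire
contract. The default pools are six bivalent donor+acceptor ring scaffolds
and eight ether-linked left / eight acyl-linked right fragments, chosen so
every junction is retrosynthetically cleavable (the library can be taken
apart by the same rules that built it) and so hydrophobe groups never
bridge a junction (coverage stays on the scaffold).

Passing on these fixtures therefore shows that extraction, classification,
joining and counting are *internally consistent and exactly invertible* on
inputs that satisfy the model's assumptions. It does not show robustness
to real docking output: strained conformations, partial matches, fused
peripheries, tautomers and perception disagreements all live outside the
generator's world. The noise parameter probes the geometric margin only.

## Numerical and degenerate-input choices

* Canonicalization is constitutional: coordinates are dropped before
  canonical SMILES generation, so stereodescriptors perceived from 3D
  geometry never enter scaffold or fragment identity. Deduplication at
  2D-substructure level is the package-wide convention.
* Charges: neutralization sets formal charges to zero wherever the
  resulting valence is legal (hydrogen counts re-derive automatically);
  impossible cases (quaternary N) stay charged and are flagged, before
  deduplication.
* Molecules with no cleavable bond yield a single zero-port candidate that
  can never become a scaffold; acyclic molecules yield no scaffold at all.
  Both return `NULL` with a logged message rather than an error, because a
  hit list legitimately contains such molecules.
* Empty fragment pools give a zero count and an empty stream; a sampling
  `k` larger than a pool uses the whole pool.
* Trivalent scaffolds whose third port is not on an aromatic carbon are
  unexpandable and drop out of the final set, logged.
* The CLI distinguishes usage errors (exit 1) from data errors (exit 2)
  and can write a JSON run report of inputs, seeds, counts and skips.

## Problem sizes used in the checks

The shipped checks run at deliberately small scales chosen to exercise
every code path: 50 randomized enumeration specs within 10×10×10, a
100–200 pose zero-noise fixture library for recovery, 10 paired
150-iteration generation runs for the reward comparison, and binomial
simulations at n = 400. The space-counting checks use the full headline
cardinalities (11,935 × 1,288 × 7,985) directly, since counting is
arithmetic over set sizes and needs no enumeration.

## Known limitations

* Feature perception is minimal by design; molecules relying on exotic
  donors/acceptors (e.g. C–H donors, halogen bonds) will under-match.
* BRICS compatibility is implemented for the published environment set;
  user-defined cleavage chemistry is not yet pluggable.
* The toy generator's chemistry (three mutation operators, small
  substituent pool) is a demonstration instrument; none of its diversity
  magnitudes transfer to production generative models.
* Alert tiers are starting sets; serious triage requires a curated,
  target-appropriate rule file in the same format.
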