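# edgotype

Structural interactome edgotyping and estimation of the completely
dispensable fraction of a protein–protein interaction (PPI) network.

## The problem

Interactome networks contain true physical interactions whose loss has no
measurable fitness consequence — *completely dispensable* PPIs. Estimating
how large that fraction is requires knowing, for many mutations of known
fitness class, whether each one *edgetically* disrupts specific interactions
(by hitting a binding interface) rather than destroying the protein
altogether. `edgotype` implements that whole chain for people working with
residue-resolved interaction structural models:

1. **Structural interactome construction** — starting from a reference PPI
   edge list, chain coordinates, and protein-to-chain alignment hits, binding
   interfaces are detected geometrically (a residue is interfacial when any
   of its atoms lies within 5 Å of the partner chain) and mapped back onto
   protein sequence positions. Alignments are kept below an E-value cutoff of
   1e-10, one best hit per (protein, chain); a chain-pair annotation requires
   ≥ 50% of each chain's interface residues mapped onto the protein; at most
   5 annotations with the smallest joint E-values are retained per PPI.
2. **Mutation mapping** — ClinVar-style disease records (strictly pathogenic,
   ≥ 1 review star, no conflicting interpretations) and dbSNP-style common
   records (validated, not withdrawn, no disease assertions, minor allele
   frequency > 1%) are placed on protein sequences by flanking-sequence
   verification (up to 10 residues on each side, required at the same
   position).
3. **Edgotyping** — geometry-based: a mutation disrupts a PPI iff it sits on
   the interface mediating it; physics-based: an interfacial mutation
   disrupts a PPI iff its binding free energy change satisfies
   ΔΔG > 0.5 kcal/mol (ΔΔG values are consumed as a table, e.g. BindProfX or
   FoldX output).
4. **Dispensable content** — with fitness-class priors P(N) = 0.27,
   P(M) = 0.53, P(S) = 0.20 for new missense mutations and the class-wise
   edgetic fractions P(E|N) = k_N/n_N, P(E|M) = k_M/n_M (and P(E|S) = 0,
   strongly detrimental mutations being quasi-null):

   P(E) = P(E|N)·P(N) + P(E|M)·P(M) + P(E|S)·P(S)

   P(N|E) = P(E|N)·P(N) / P(E)

   The 95% CI uses the Katz log interval for the ratio of the two
   proportions, mapped through 1/P(N|E) = {P(E|M)/P(E|N)}·{P(M)/P(N)} + 1.

A synthetic-world generator (`generate_world()`) produces internally
consistent chain coordinates, alignments, interactomes, mutation tables and
ΔΔG tables with known ground truth, so every stage is testable without any
external database. QC helpers (SimGIC functional similarity, tissue
co-expression) validate structural interactomes the way the field usually
does.

## Worked example

The headline estimate from published edgetic counts (19/376 non-disease and
27/145 disease mutations edgetic in a Y2H-derived structural interactome):

```r
library(edgotype)
est <- estimate_dispensability(edgetic_counts(k_N = 19, n_N = 376,
                                              k_M = 27, n_M = 145))
est
#> <dispensability_estimate> variant: standard
#>   P(E|N) = 19/376 = 5.1%   P(E|M) = 27/145 = 18.6%
#>   P(E)    = 11.2%
#>   P(N|E)  = 12.1%  (95% CI 7.4-19.4%)
```

So a new missense mutation has an 11.2% probability of being edgetic, and an
edgetic disruption is effectively neutral — the PPI dispensable — with
probability 12.1% (95% CI 7.4–19.4%).

The same numbers can be produced end to end from synthetic data with known
truth:

```r
cfg <- synthetic_world_config(n_proteins = 40, n_ppis = 30,
                              mean_protein_length = 120, interface_width = 8,
                              n_disease_mut = 400, n_nondisease_mut = 400,
                              seed = 1)
world <- generate_world(cfg)
res <- run_pipeline(world)
res$counts_geometry
#> <edgetic_counts> non-disease 19/400 (4.8%), disease 82/400 (20.5%)
res$estimate_geometry
#> <dispensability_estimate> variant: standard
#>   P(E|N) = 19/400 = 4.8%   P(E|M) = 82/400 = 20.5%
#>   P(E)    = 12.1%
#>   P(N|E)  = 10.6%  (95% CI 6.8-16.0%)
```

The configured truth here was P(E|N) = 0.051, P(E|M) = 0.186 and class-wise
disruption probabilities γ_N = 0.60, γ_M = 0.66; the pipeline recovers
γ_N = 0.63 and γ_M = 0.72 on this 800-mutation world, within binomial
sampling error.

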