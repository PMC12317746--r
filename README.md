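# nicheMNN

Joint spatial-domain detection across multiple spatially resolved
transcriptomics (SRT) samples, for analysts who have several tissue
sections — Visium, STARmap, MERFISH, or similar — and want one consistent
set of domain labels over all of them without physical section alignment
and without per-sample clustering followed by manual label matching.

## Method

The pipeline is a two-stage graph algorithm over units (spots or cells)
with counts $X_{M\times G}$ and 2D coordinates.

**Stage 1 (per sample, parallelizable).** Counts become null-model
residuals — deviance residuals under $\mu_{ij} = n_i\pi_j$ — followed by
centered PCA to $Y_{M\times N}$ ($N = 30$ PCs). A spatial kNN graph
($k = 6$, Euclidean, union-symmetrized) is weighted by expression
similarity and pruned: the default *smoothed* weight of edge $(u,v)$ is

$$ W_e = \mathrm{Corr}\big(\mathrm{Avg}(Y_{(V_u - V_u\cap V_v)\cup\{u\}}),\ \mathrm{Avg}(Y_{(V_v - V_v\cap V_u)\cup\{v\}})\big) $$

with $V_u, V_v$ the endpoints' $q$ spatially nearest neighbours, and
edges with $W_e < 0.6$ are removed. Louvain at high resolution (10)
partitions the pruned graph into 100–200 *niches* per ~5000-unit sample;
niches smaller than 5 units are merged into their spatial surroundings,
and counts are summed per niche (pseudobulk).

**Stage 2 (across samples).** All niches are embedded jointly (Pearson
residuals + PCA on the common gene set), and niches $u$, $v$ of different
samples are connected iff they are mutual nearest neighbors
($u \in V_v$ and $v \in V_u$, $k_{\mathrm{mnn}} = 15$ per target sample).
Louvain at resolution 1 on this MNN graph yields the spatial domains,
which propagate to every unit through its niche. Mutuality is what makes
the integration robust to sample-wise batch shifts.

The package also provides the evaluation metrics ARI, NMI and a landmark
co-localization index, and a two-phase multi-sample simulator (layered /
ringed / quadrant tissue patterns, tissue-by-cell-type mixture matrix,
200 marker genes per type, 10% noisy genes, Gaussian noise with
configurable per-sample batch shift and variance) with full ground truth.

## Worked example

```r
library(nicheMNN)

sims <- simulate_dataset(sim_config(n_samples = 2, seed = 5))
sims[[1]]
#> srt_sample 'sample_1': 4992 units x 889 genes (annotated)

res <- run_pipeline(sims, run_config(seed = 5), workers = 2)
res
#> pipeline_result: 2 sample(s), 331 niches, 1933 MNN edges, 8 domains

truth <- unlist(lapply(sims, function(s) s$truth$region))
pred  <- unlist(lapply(names(res$assignment$unit_domain), function(sid)
  res$assignment$unit_domain[[sid]][sims[[sid]]$unit_ids]))
sprintf("pooled ARI = %.3f, NMI = %.3f", ari(truth, pred), nmi(truth, pred))
#> "pooled ARI = 0.844, NMI = 0.813"
```

The two simulated samples have four true tissue regions in horizontal
layers. Stage 1 compresses each sample to ~165 niches; stage 2 links them
with 1933 mutual-nearest-neighbor edges and finds domains shared by both
samples. The four largest domains carry almost all units and match the
four regions (pooled ARI 0.844); the remaining small domains collect
boundary and pruning-isolated niches. `res$assignment$niche_domain` maps
every (sample, niche) to its domain, `res$assignment$unit_domain` every
unit; `write_labels()` exports a tidy `sample_id,unit_id,x,y,domain` CSV.

A command-line front end with the same defaults lives at
`inst/cli/nichemnn.R`:

```sh
Rscript inst/cli/nichemnn.R simulate --n-samples 4 --seed 1 --out sim/
Rscript inst/cli/nichemnn.R run --input manifest.csv --out out/ --threads 4
Rscript inst/cli/nichemnn.R benchmark --pred out/domains.csv --truth sim/truth.csv
```

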