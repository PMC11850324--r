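# kgrdr

Drug–disease association prediction that fuses two complementary views of
drugs and diseases:

* an **attribute view** `X`, obtained by selecting, denoising and jointly
  decomposing many drug–drug / disease–disease similarity matrices
  (KL-divergence joint factorization with graph-Laplacian regularization,
  `min Σ_v KL(S̃⁽ᵛ⁾ ‖ softmax(XW⁽ᵛ⁾ᵀ)) + λ Σ_v Tr(XᵀL̃⁽ᵛ⁾X)`);
* a **topological view** `Y`, the `[Re ‖ Im]` features of complex-valued
  knowledge-graph embeddings trained with the ComplEx trilinear score
  `φ(s,r,o) = Re⟨w_r, e_s, ē_o⟩` and a logistic loss with negative
  sampling.

The two views are combined by iterative attentional feature fusion
(multi-scale channel attention gates, `Z = M(X⊎Y)⊗X + (1−M(X⊎Y))⊗Y`) and
fed to a heterogeneous graph convolutional network: kNN similarity graphs
for drugs and diseases, intra-domain GCN layers, inter-domain bilinear
aggregation, residual merging, layer attention, and a bilinear sigmoid
decoder `Â = σ(H_R H_Dᵀ)` trained with class-balanced binary
cross-entropy (`γ = |S⁻|/|S⁺|`, Adam).

Everything runs on plain-text inputs (dense similarity TSVs, an
interaction TSV, a 3-column triples TSV) and the package ships a seeded
synthetic-data generator that plants a low-rank association structure so
the whole pipeline is testable offline.  See the methods vignette
(`vignettes/kgrdr-methods.Rmd`) for the model, the numerical choices and
the known limitations.

## Worked example

```r
library(kgrdr)

# a seeded synthetic benchmark: 16 drugs x 12 diseases, planted rank-2
# structure, 2 similarity views per side plus a duplicate and a noise view
spec <- fixture_spec(n_drugs = 16, n_diseases = 12, latent_rank = 2,
                     density = 0.15, n_views_drug = 2, n_views_disease = 2,
                     redundancy_copies = 1, noise_view = TRUE,
                     kg_extra_relations = 1, seed = 1)
dir <- tempfile()
paths <- write_fixture(spec, dir)

cfg <- run_config(epoch = 200, embedding_dim = 8, GR_dim = 8, KG_dim = 8,
                  kg_epochs = 50, topk = 5, seed = 1)
res <- run_pipeline(cfg, list(interactions = paths$interactions,
                              kg = paths$kg,
                              drug_sims = paths$drug_sims,
                              disease_sims = paths$disease_sims),
                    out_dir = file.path(dir, "run"))

interactions <- read_interactions_tsv(paths$interactions)
rank_candidates(res$scores, interactions, "DI001", top_n = 3)
```

```
  disease_id drug_id      score rank
1      DI001   DR011 0.88424444    1
2      DI001   DR001 0.05483643    2
3      DI001   DR013 0.05347449    3
```

The three rows are the highest-scoring drugs *not* already associated
with disease `DI001`: candidate repositioning hypotheses, with `score`
the decoder probability `Â_ij` that the association exists.  The run
directory holds the integrated features (`X_*.tsv`), the knowledge-graph
features (`Y_*.tsv`), the fused features (`Z_*.tsv`), the full score
matrix (`scores.tsv`), the per-epoch loss (`loss_trace.csv`), the
resolved configuration (`config.json`) and an I/O audit log.

A command-line interface wraps the same stages:

```sh
kgrdr simulate --out data/ --seed 1
kgrdr cv --interactions data/interactions.tsv --kg data/kg_triples.tsv \
         --drug_sims data/sim_drugs_01.tsv,data/sim_drugs_02.tsv \
         --disease_sims data/sim_diseases_01.tsv --out run/ --seed 1
kgrdr predict --scores run/scores.tsv --interactions data/interactions.tsv \
              --disease DI001 --top 10
```

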