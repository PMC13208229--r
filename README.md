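# nncopula

Privacy-preserving synthetic **dichotomous item response data** with a
neural network copula, plus the 2PL item response theory (IRT) toolkit and
the four-facet validation framework needed to certify that the synthetic
data are psychometrically faithful.

## The problem

Item response matrices from cognitive and educational assessments — one
row per examinee, one 0/1 column per item — usually cannot be shared.
Classic parametric IRT simulation (fit a 2PL, resample abilities, redraw
responses) protects privacy but destroys every dependence feature the 2PL
does not model. `nncopula` instead separates the two ingredients a copula
separates:

* **margins** — each item's proportion correct, preserved *exactly by
  construction* through an inverse threshold transform;
* **dependence** — learned non-parametrically by a deep autoencoder on
  pseudo-uniform variates.

The generator pipeline is:

1. **Randomized probability integral transform.** Each response becomes a
   uniform draw on the sub-interval its value occupies:
   `U_ik ~ Unif(1 - p_k, 1)` if `Y_ik = 1`, `U_ik ~ Unif(0, 1 - p_k)`
   otherwise. Columns are exactly Uniform(0,1); dependence survives.
2. **Autoencoder.** Encoder `K -> 256 -> 128 -> 64 -> d` (batch norm,
   ReLU, dropout 0.2; linear latent head), mirrored decoder ending in a
   sigmoid. Loss `L = L_recon + 0.1 * L_marginal`, where the marginal term
   anchors reconstructed column means at 0.5. Adam, plateau learning-rate
   halving, early stopping with best-epoch restoration.
3. **Latent KDE.** An isotropic Gaussian kernel density (bandwidth
   `h = 0.2`) over the training latent codes; new codes are exact draws
   from the mixture.
4. **Inverse transform.** Decoded rows are thresholded at
   `1 - p_k` (training margins), so `E[Y_syn] = p_k` item by item.

Validation follows four facets: data-level consistency (total-score
moments, marginal MAD, inter-item correlation RMSR), psychometric
recovery (2PL parameter r/MAD/RMSD, test information and conditional
standard error profiles, Infit/Outfit), inferential precision
(Monte-Carlo vs asymptotic standard errors over replicated generation),
and cross-seed stability (full retraining per seed).

The 2PL machinery is self-contained: marginal maximum likelihood EM with
41-node Gauss–Hermite quadrature, EAP scoring, per-item Fisher-information
standard errors, and Infit/Outfit mean squares.

## Worked example

```r
library(nncopula)

# a simulated 20-item assessment, ~5000 examinees, 2PL ground truth
sim   <- simulate_2pl(sim_design(n = 5069, K = 20, seed = 11))
parts <- stratified_partition(sim$Y, seed = 5)   # 64/16/20 by score decile

model <- nnc_train(parts$train, parts$validation, nnc_config(), seed = 42)
model
#> Neural network copula model: 20 items, trained on 3243 examinees
#>   best epoch 196 of 216 | val loss 0.005405
#>   latent d = 20 | kde h = 0.2 (Silverman ref 1.01 )

synth  <- nnc_generate(model, seed = 42)         # 3243 synthetic examinees
report <- validate_synthetic(parts$train, synth, seed = 1)
report
#> Synthetic-data validation report (schema 1.0 )
#>   marginal: MAD 0.013 | mean rel % 2.444 | r 0.994
#>   dependence RMSR 0.022
#>   a: r 0.974 MAD 0.085 RMSD 0.100 | b: r 0.992 MAD 0.090 RMSD 0.118
#>   r(TIF) 0.998 | r(CSEM) 0.999 | mean |Infit diff| 0.0068
```

Reading the report: synthetic item proportions deviate from the training
proportions by 0.013 on average (MAD) and the inter-item correlation
matrices differ by RMSR 0.022 — below the 0.05 conventional good-fit bar.
Refitting the 2PL on the synthetic data reproduces the difficulty ranking
almost perfectly (r = 0.992) and the discrimination ranking strongly
(r = 0.974); the test information and conditional-standard-error profiles
are nearly indistinguishable (r ≥ 0.998), and item fit statistics move by
less than 0.01 on average. Monte-Carlo precision and cross-seed stability
are available through `mc_precision()` and `stability_facet()`, and
`sensitivity_driver()` sweeps the latent dimension and KDE bandwidth
grids.

A thin command-line front end (`inst/cli/nnc.R`) exposes
`simulate`, `fit-irt`, `train`, `generate`, and `validate` subcommands
over the same functions.

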