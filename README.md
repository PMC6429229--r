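# cpqsar

Counter-propagation neural network QSAR modelling with consensus
predictions and applicability domains.

`cpqsar` is for cheminformaticians building ligand-based models of
membrane-transporter activity — the setting where a transporter such as
bilitranslocase has in vitro inhibition constants (pKi, Ki in mmol/L)
for a modest compound set, and the goal is to classify untested
compounds as inhibitors (active iff pKi > 1.3) and to predict pKi for
the actives. The package implements the full modelling protocol:

* **Preprocessing** — autoscaling (population-SD convention),
  zero-variance and intercorrelation (|r| > 0.9) filters, Kohonen-map
  similarity reduction of the descriptor pool, SOM-based or stratified
  train/validation splitting (75/25 or 60/25/15).
* **Models** — counter-propagation artificial neural networks (a Kohonen
  map with a counter-propagated output layer; winner lookup, triangular
  neighbourhood, linear learning-rate decay) and multiple linear
  regression, each with its applicability domain: maximal training
  Euclidean distance to the winning neuron (ED_crt) for the networks,
  the leverage threshold hat\* = 3(p+1)/n for MLR.
* **Descriptor selection** — a genetic algorithm over binary descriptor
  masks with cross-validated fitness, tournament selection, uniform
  crossover, size repair and elitism.
* **Consensus** — agreement-typed classification consensus (A: complete
  agreement; B: exactly one dissent among three models; out-of-domain
  models abstain) and the leverage-weighted regression consensus
  ȳw = Σ(yₖ/hₖ)/Σ(1/hₖ).
* **Validation** — SE, SP, NPV, PPV, MCC, prediction rate, standard and
  balanced accuracy, ROC/AUC, and the external regression suite R²,
  RMSE, Q²F3, Lin's CCC, rm².
* **Synthetic data** — a generator reproducing the statistical shape of
  a 120-compound transporter study (50/70 class split at pKi 1.3,
  planted linear + mild product-term signal on 5 of 40 descriptors,
  correlated near-duplicate blocks, a 300-compound screening set), so
  every stage is testable without commercial descriptor software.

Everything is tibble-first: descriptor tables are data frames whose
first column is `compound_id`, predictions come back as tibbles, fitted
objects have `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

Indicator arithmetic works straight from confusion tallies — here a
single classifier's counts over a 120-compound set:

```r
library(cpqsar)
q <- quality_indicators(confusion_from_counts(TP = 44, TN = 61,
                                              FP = 9, FN = 6,
                                              n_total = 120))
round(q[, c("SE", "SP", "acc_standard", "NPV", "PPV", "MCC", "PR")], 2)
#>     SE   SP acc_standard  NPV  PPV  MCC PR
#> 1 0.88 0.87         0.88 0.91 0.83 0.75  1
```

SE = 44/50 of true actives recovered, SP = 61/70 of inactives, and
MCC = 0.75 summarizes the balance; PR = 1 because every compound
received a prediction. The leverage applicability threshold for an
11-descriptor MLR trained on 90 compounds is `hat_star(11, 90)`, i.e.
exactly `0.4`.

End to end on synthetic data:

```r
d <- simulate_qsar_dataset(qsar_spec(seed = 7))
d
#> <qsar_dataset> 120 compounds x 40 descriptors; 50 active / 70 inactive (pKi > 1.3)

xs <- autoscale(d$descriptors[c("compound_id", d$true_support)])
m  <- train_cpann(xs, d$activities$class,
                  cpann_config(grid_rows = 8, grid_cols = 8,
                               epochs = 100, seed = 2))
m
#> <cpann> classification map 8x8, 5 descriptors, 100 epochs, ED_crt = 1.678

mean(predict(m, xs)$prediction == d$activities$class)
#> [1] 0.8666667
```

`ED_crt = 1.678` is the largest distance of any training compound to its
winning neuron — queries farther out are flagged outside the
applicability domain. The full protocol (filters, similarity reduction,
GA selection, three classifier roles, four regression networks, the
validation report and consensus calls) is one call:

```r
battery <- run_modeling_pipeline(d, seed = 1)
profile <- run_screening(battery,
                         simulate_screening_set(d, n = 300, seed = 2))
screening_summary(profile)
```

See `vignettes/cpqsar-methods.Rmd` for the model descriptions,
parameter rationale, and the generator's scope and limitations.

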