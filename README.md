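# ProtStress

Binary classification of abiotic-stress-responsive proteins (cold, drought,
heat, salt) from amino-acid sequence features, built around the **SIELU**
activation function — the tanh-form GELU rewritten through the sigmoid
identity — together with the classical normal-distribution approximations it
descends from.

For plant researchers and breeders who have protein sequences in FASTA and
want a reproducible, scriptable classifier (and for anyone who wants a
tested, self-contained implementation of the SIELU/GELU numerics).

## The core in one screen

The activation:

    SIELU(x) = x · σ( 2·√(2/π) · (x + 0.044715·x³) )
    GELU (x) = 0.5·x · [ 1 + tanh( √(2/π) · (x + 0.044715·x³) ) ]

These are the same function (tanh(y) = 2σ(2y) − 1); the package proves it
operationally — identical values to < 1e−12 on a dense grid, and identical
training trajectories for seeded networks differing only in activation.

The pipeline: FASTA → sanitize → 46-feature encoding (residue composition,
coiled-coil score, PTM motif counts, length/charge/mass/pI, atom counts,
instability index, aliphatic index, GRAVY) → greedy 80%-identity
deduplication → stratified 80:20 split (nested 80:20 train/validation) →
z-standardization fitted on train → a 46-150-50-1 network (He-normal init,
0.02 dropout, Adam, MSE-on-sigmoid, 500 epochs) with SVM (polynomial
kernel, coefficient 0.01) and random-forest baselines → accuracy,
precision, recall, F1, specificity (percent) and MCC, plus PR/ROC curves.

## Worked example

```r
library(ProtStress)

sielu(c(-2, -1, 0, 1, 2))
#> [1] -0.04540231 -0.15880801  0.00000000  0.84119199  1.95459769

v <- extractFeatures("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
round(v[c("comp_K", "length", "n_positive", "molecular_weight",
          "theoretical_pI", "instability_index", "gravy")], 4)
#>            comp_K            length        n_positive  molecular_weight
#>            0.0909           33.0000            6.0000         3935.6031
#>    theoretical_pI instability_index             gravy
#>           10.6241           53.5485           -0.4030
```

The length-33 peptide is 9.1% lysine, carries 6 positive residues (hence the
basic pI of 10.6), weighs 3.94 kDa, scores 53.5 on the instability index
(> 40 = predicted unstable) and is mildly hydrophilic (GRAVY −0.40).

End to end on synthetic data with planted signal (class 1 has a +0.10
lysine composition shift and planted SUMO motifs):

```r
ds  <- generateSequences(generatorSpec(nPerClass = 100, seed = 1))
res <- runPipeline(seqRecords(ds), classLabels(ds),
                   config = modelConfig(epochs = 200, seed = 1), seed = 1)
lapply(res$metrics, function(m) lapply(m$test, round, 2))
#> $net — accuracy 97.5, precision 95.24, recall 100, f1 97.56,
#>        specificity 95, mcc 0.95
#> $svm — all 100, mcc 1
#> $rf  — all 100, mcc 1
```

All three models recover the planted signal on the held-out 20%; the
network's one false positive out of 40 test sequences is what accuracy
97.5% / specificity 95% means here.

The historical approximation scans:

```r
errorScan(cdfCompositeExponential, function(z) exactNormalCdf(z) - 0.5,
          0, 10, 1e-4)
#> ErrorScanReport on [0, 10] (step 0.0001)
#>   max |error| = 3.03652e-05 at 0.4017
```

(The composite-exponential CDF approximation's measured maximum error is
3.04e−5, marginally above its traditionally quoted 3e−5 bound; the rational
inverse-normal approximation meets its 4.5e−4 bound with measured maximum
4.44e−4. See the methods vignette.)

## Command line

A thin dispatcher over the same functions ships in `inst/scripts/protstress`:

```sh
protstress prepare  --positive pos.fasta --negative neg.fasta --out run/ --stress-class salt
protstress train    --dir run/ --activation sielu --epochs 500
protstress evaluate --dir run/
protstress predict  --fasta new.fasta --dir run/ --out predictions.csv
protstress benchmark-activations --out scan.json
```

Every command is seed-deterministic and writes a manifest describing its
inputs and configuration.

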