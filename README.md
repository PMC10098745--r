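# coaxperm

Complex permittivity extraction and group statistics for coaxial-cell
dielectric spectroscopy of liver tissue.

Microwave dielectric properties separate healthy from fatty (steatotic)
liver: *ex-vivo* mouse liver shows a real relative permittivity near
**ε′ ≈ 42** for healthy tissue and **ε′ ≈ 31** for fatty tissue at 1 GHz,
with the loss part ε″ diminished by about 35%. `coaxperm` implements the
complete computational chain that turns bench measurements into those
numbers, for anyone running a two-port coaxial transmission-line cell with a
vector network analyzer (VNA):

1. **De-embedding.** A specimen session produces three two-port S-parameter
   sweeps: the sample measurement, a short-circuit reference, and an
   empty-cell reference. The reference planes are moved to the sample faces
   by magnitude/phase correction,

   |S<sub>ii</sub><sup>s</sup>| = |S<sub>ii</sub><sup>m</sup>| / |S<sub>ii</sub><sup>sc</sup>|,  |S<sub>ij</sub><sup>s</sup>| = |S<sub>ij</sub><sup>m</sup>| / |S<sub>ij</sub><sup>em</sup>|,
   φ<sub>ii</sub> = φ<sub>ii</sub><sup>m</sup> − φ<sub>ii</sub><sup>sc</sup> − π,  φ<sub>ij</sub> = φ<sub>ij</sub><sup>m</sup> − φ<sub>ij</sub><sup>em</sup> − kL,

   with k = ω/c₀ and L the sample-holder length.

2. **Nicolson–Ross extraction.** From the sample-plane S₁₁, S₂₁ the
   interface reflection Γ (the quadratic root with |Γ| ≤ 1) and the
   transmission factor T give, for a non-magnetic sample,

   ε = (i c₀ ln T)/(ωL) · (1 − Γ)/(1 + Γ),  ln T = ln|T| + i(arg T + 2πn),

   with explicit control of the logarithm branch n (fixed principal branch,
   or frequency-continuity unwrapping for electrically long samples).

3. **Cohort statistics.** Per-group spectral means with s.e.m. and a ±10%
   repeatability band, percent diminutions between groups, a Shapiro–Wilk +
   two-tailed unpaired (pooled) t-test chain, and the permittivity-vs-hepatic
   biochemistry association table.

Because no raw VNA data are deposited for this kind of study, the package
also contains a first-class **synthetic cohort generator**: per-animal Debye
tissue models calibrated to the group anchors (42 ± 2 healthy, 31 ± 3 fatty
at 1 GHz), exact TEM forward modelling of the measuring cell (L = 3 mm,
d₁ = d₂ = 96 mm air lines), VNA-style instrument noise, and biochemistry
covariates (hepatic triglycerides and glucose) with the group overlap
structure of a real high-fat/high-sugar (HFS) diet experiment. Every stage
of the pipeline is therefore testable end to end.

Sign convention throughout: time dependence e^{+iωt}, ε = ε′ − iε″, so
passive media have ε″ ≥ 0.

## Worked example

Noiseless single-specimen round trip through the full chain:

```r
library(coaxperm)

f   <- defaultFrequencyGrid()              # 100 MHz - 2 GHz, 191 points
eps <- evaluatePermittivity(healthyLiverModel(), f)
ms  <- synthesizeMeasurementSet(eps, cellGeometry())   # sample/short/empty
rec <- extractPermittivity(deembedSParams(ms), 0.003)
rec
#> PermittivitySpectrum: 191 points, 1e+08-2e+09 Hz
#>   eps' range: [41.58, 42.14]; eps'' range: [8.965, 90.1]
Re(epsilonAt(rec, 1e9))      # 41.998  <- the healthy-liver 1 GHz anchor
-Im(epsilonAt(rec, 1e9))     # 11.249  <- loss part at 1 GHz
```

A full synthetic cohort (6 control + 10 HFS animals, default instrument
noise) analysed at 1 GHz:

```r
co      <- generateCohort(cohortConfig(seed = 1))
spectra <- extractCohortSpectra(co)
grp     <- vapply(co, function(s) s@group, character(1))

sc <- summarizeGroupSpectra(spectra[grp == "control"], "control")
sh <- summarizeGroupSpectra(spectra[grp == "HFS"], "HFS")
sc
#> GroupSpectraSummary 'control': n = 6, 191 frequencies
#>   near 1e+09 Hz: eps' = 42.81 +/- 0.79 (sem), eps'' = 11.25 +/- 0.34
sh
#> GroupSpectraSummary 'HFS': n = 10, 191 frequencies
#>   near 1e+09 Hz: eps' = 30.41 +/- 0.58 (sem), eps'' = 7.24 +/- 0.22

percentDiminution(sc, sh, 1e9, "real")   # 28.97 (% drop of eps' in HFS)
percentDiminution(sc, sh, 1e9, "imag")   # 35.65 (% drop of eps'')

e1 <- vapply(spectra, function(s) Re(epsilonAt(s, 1e9)), numeric(1))
compareGroups(e1[grp == "control"], e1[grp == "HFS"])$t_test
#> t = 12.85, df = 14, p = 3.9e-09   -> groups separate decisively

associationAtFrequency(co, 1e9, spectra)$pearson
#>      tg_liver glucose_liver
#>        -0.977        -0.422   -> permittivity falls as hepatic TG rises
```

The group means sit on the anchors within sampling error, the loss-part
diminution is ~35%, and permittivity is strongly negatively associated with
hepatic triglycerides while the glucose ranges overlap — the structure that
makes the dielectric measurement diagnostically useful where biochemistry
alone is ambiguous.

## Command line

A thin CLI over the same functions lives at `inst/cli/coaxperm.R`
(`system.file("cli", "coaxperm.R", package = "coaxperm")`); its subcommands
compose into the whole pipeline on disk:

```sh
coaxperm.R simulate --config cohort.yaml --out fixtures/
coaxperm.R deembed  --measurement m.s2p --short sc.s2p --empty em.s2p \
                    --length-mm 3 --d1-mm 96 --d2-mm 96 -o sample.s2p
coaxperm.R extract  --input sample.s2p --length-mm 3 --branch 0 -o spectrum.csv
coaxperm.R analyze  --spectra spectra/ --metadata fixtures/cohort.csv --out analysis/
```

Sweeps interchange as Touchstone v1 `.s2p` (Hz/kHz/MHz/GHz units, RI/MA/DB
formats), spectra as CSV (`frequency_hz, eps_real, eps_imag, branch_n,
flags`), configs as YAML.

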