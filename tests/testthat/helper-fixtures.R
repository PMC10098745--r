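# Shared fixtures, built in code at test time.

# short grid that still contains 1 GHz exactly
tinyGrid <- function() c(1e8, 5.5e8, 1e9, 1.5e9, 2e9)

constSpectrum <- function(eps, f = tinyGrid()) {
  permittivitySpectrum(f, rep(as.complex(eps), length(f)))
}

# random passive permittivity value: eps' in [2, 80], tan(delta) in [0, 1]
randomEps <- function() {
  epsr <- runif(1, 2, 80)
  complex(real = epsr, imaginary = -epsr * runif(1, 0, 1))
}

# noiseless measurement pipeline: model/eps spectrum -> recovered spectrum
recoverSpectrum <- function(eps, geom = cellGeometry(),
                            opts = nrwOptions()) {
  ms <- synthesizeMeasurementSet(eps, geom)
  extractPermittivity(deembedSParams(ms), geom@L, opts)
}
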