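#' @include deembed.R
NULL

#' Options for the Nicolson-Ross extraction
#'
#' @param branchIndex Integer logarithm-branch index `n` applied to
#'   \eqn{\ln T = \ln|T| + i(\arg T + 2\pi n)}; `|n| <= 10`. For the default
#'   cell (L = 3 mm) and tissue-like permittivity below 2 GHz the sample's
#'   electrical phase never reaches \eqn{\pi}, so the principal branch
#'   `n = 0` is correct.
#' @param branchMode `"fixed"` uses `branchIndex` at every frequency;
#'   `"continuity"` seeds the lowest frequency with `branchIndex` and then
#'   picks `n` per frequency to minimize the jump
#'   \eqn{|\epsilon(f_k)-\epsilon(f_{k-1})|} (needed once the sample is
#'   electrically longer than half a wavelength).
#' @param rootRule Reflection-root rule; only `"magnitude"` (keep the root
#'   with \eqn{|\Gamma| \le 1}, deterministic impedance-sign tie-break on
#'   the lossless \eqn{|\Gamma| = 1} edge) is defined.
#' @param portAverage `"off"` uses S11 and S21 as given; `"reciprocal-mean"`
#'   first averages the reciprocal pairs (arithmetic mean of S11/S22,
#'   geometric mean of S21/S12) — useful on noisy measured data.
#' @return Named list of validated options.
#' @export
nrwOptions <- function(branchIndex = 0L,
                       branchMode = c("fixed", "continuity"),
                       rootRule = "magnitude",
                       portAverage = c("off", "reciprocal-mean")) {
  branchIndex <- as.integer(branchIndex)
  if (abs(branchIndex) > 10L) stop("branchIndex must satisfy |n| <= 10")
  rootRule <- match.arg(rootRule)
  list(branchIndex = branchIndex, branchMode = match.arg(branchMode),
       rootRule = rootRule, portAverage = match.arg(portAverage))
}

# Reflection-root candidates via X = (S11^2 - S21^2 + 1)/(2 S11),
# Gamma = X +/- sqrt(X^2 - 1). Vectorized; assumes s11 != 0.
.gammaFromX <- function(s11, s21) {
  X <- (s11^2 - s21^2 + 1) / (2 * s11)
  r <- sqrt(X^2 - 1)
  cbind(X + r, X - r)
}

# Same roots via the product form C = sqrt((S11+S21+1)(S11+S21-1)
# (S11-S21+1)(S11-S21-1)); C^2 = (S11^2-S21^2+1)^2 - 4 S11^2, so
# (X^2-1) = C^2/(2 S11)^2 and the two forms coincide up to the sign of the
# radical, which the magnitude rule re-selects anyway.
.gammaFromC <- function(s11, s21) {
  C <- sqrt((s11 + s21 + 1) * (s11 + s21 - 1) *
            (s11 - s21 + 1) * (s11 - s21 - 1))
  num <- s11^2 - s21^2 + 1
  cbind((num - C) / (2 * s11), (num + C) / (2 * s11))
}

# Pick the physical root per frequency: |Gamma| <= 1; on the lossless
# |Gamma| = 1 edge (the two candidates are reciprocal, so their moduli
# straddle 1 otherwise), keep the root with non-negative real normalized
# wave impedance Re((1-Gamma)/(1+Gamma)) >= 0.
.pickRoot <- function(cand, tol = 1e-9) {
  m1 <- Mod(cand[, 1]); m2 <- Mod(cand[, 2])
  g <- ifelse(m1 <= m2, cand[, 1], cand[, 2])
  tie <- abs(m1 - m2) < 1e-12
  if (any(tie)) {
    alt <- ifelse(m1 <= m2, cand[, 2], cand[, 1])
    zneg <- Re((1 - g) / (1 + g)) < 0
    swap <- tie & zneg
    g[swap] <- alt[swap]
  }
  if (any(Mod(g) > 1 + tol))
    stop("no passive reflection root: both candidates have |Gamma| > 1")
  g
}

#' Select the physical interface reflection coefficient
#'
#' Solves the Nicolson-Ross quadratic for the air/sample interface
#' reflection \eqn{\Gamma} from one (S11, S21) pair and returns the root
#' with \eqn{|\Gamma| \le 1}. The two candidate roots are reciprocal
#' (\eqn{\Gamma} and \eqn{1/\Gamma}), so exactly one is physical for a lossy
#' sample; on the lossless edge where both have unit modulus the root with
#' non-negative real wave impedance is kept.
#'
#' @param s11,s21 Complex reflection and transmission coefficients (may be
#'   vectors of equal length).
#' @return Complex \eqn{\Gamma}, same length as the inputs.
#' @examples
#' sw <- sampleSParams(permittivitySpectrum(1e9, 4 + 0i), 0.003)
#' selectReflectionRoot(sParam(sw, "s11"), sParam(sw, "s21"))  # -1/3
#' @export
selectReflectionRoot <- function(s11, s21) {
  if (any(s11 == 0))
    stop("matched sample (S11 = 0): reflection root undefined, ",
         "use the transmission-only path")
  .pickRoot(.gammaFromX(s11, s21))
}

#' Extract complex permittivity from sample-plane S-parameters
#'
#' Closed-form Nicolson-Ross inversion of a de-embedded two-port sweep for a
#' non-magnetic sample (\eqn{\mu_r = 1} imposed): per frequency, the
#' interface reflection \eqn{\Gamma} comes from [selectReflectionRoot()],
#' the transmission factor from
#' \eqn{T = (S_{11}+S_{21}-\Gamma)/(1-(S_{11}+S_{21})\Gamma)}, and
#' \deqn{\epsilon = \frac{i\,c_0 \ln T}{\omega L}\cdot
#'   \frac{1-\Gamma}{1+\Gamma}, \qquad
#'   \ln T = \ln|T| + i(\arg T + 2\pi n)}
#' (the product of the transmission-derived and reflection-derived
#' \eqn{\sqrt{\epsilon}} estimates, exact for TEM propagation). Matched
#' frequencies (\eqn{S_{11} = 0}, an \eqn{\epsilon = 1} sample) fall back to
#' the transmission-only path \eqn{\epsilon = (i c_0 \ln T / (\omega L))^2}.
#'
#' Frequencies where \eqn{|T| \ge 1} for a nominally passive sample (a
#' noise artifact) are flagged (flag 1) with a warning, not treated as
#' errors; \eqn{T = 0} is a hard error.
#'
#' @param sample A [TwoPortSweep-class] at the sample reference planes.
#' @param L Sample length, metres.
#' @param opts Options from [nrwOptions()].
#' @return A [PermittivitySpectrum-class] with per-frequency branch indices
#'   and diagnostic flags.
#' @examples
#' truth <- permittivitySpectrum(1e9, 4 + 0i)
#' extractPermittivity(sampleSParams(truth, 0.003), 0.003)
#' @export
extractPermittivity <- function(sample, L, opts = nrwOptions()) {
  stopifnot(is(sample, "TwoPortSweep"), L > 0)
  f <- sample@frequencies
  w <- 2 * pi * f

  if (opts$portAverage == "reciprocal-mean") {
    s11 <- (sample@s11 + sample@s22) / 2
    gm <- sqrt(sample@s21 * sample@s12)
    # geometric mean is sign-ambiguous; keep the root nearer S21
    flip <- Mod(gm - sample@s21) > Mod(-gm - sample@s21)
    gm[flip] <- -gm[flip]
    s21 <- gm
  } else {
    s11 <- sample@s11
    s21 <- sample@s21
  }

  matched <- Mod(s11) < 1e-10
  G <- complex(real = numeric(length(f)))
  if (any(!matched))
    G[!matched] <- .pickRoot(.gammaFromX(s11[!matched], s21[!matched]))

  T <- (s11 + s21 - G) / (1 - (s11 + s21) * G)
  if (any(Mod(T) == 0))
    stop("singular transmission factor (T = 0) at ",
         f[which(Mod(T) == 0)[1]], " Hz")

  flags <- integer(length(f))
  hot <- Mod(T) >= 1 + 1e-6
  if (any(hot)) {
    flags[hot] <- 1L
    warning("|T| >= 1 at ", sum(hot),
            " frequencies (flagged; noise artifact for a passive sample)")
  }

  # eps(n) = (z0 + n * dz) * q is affine in the branch index n
  lnT0 <- log(Mod(T)) + 1i * Arg(T)
  z0 <- 1i * .c0 * lnT0 / (w * L)
  dz <- -2 * pi * .c0 / (w * L)        # contribution of one 2*pi*n step
  q <- ifelse(matched, z0, (1 - G) / (1 + G))

  if (opts$branchMode == "fixed") {
    n <- rep(opts$branchIndex, length(f))
  } else {
    n <- integer(length(f))
    n[1] <- opts$branchIndex
    prev <- (z0[1] + n[1] * dz[1]) * q[1]
    nc <- -10:10
    for (k in seq_along(f)[-1]) {
      epsc <- (z0[k] + nc * dz[k]) * q[k]
      n[k] <- nc[which.min(Mod(epsc - prev))]
      prev <- epsc[which.min(Mod(epsc - prev))]
    }
  }
  eps <- (z0 + n * dz) * q

  permittivitySpectrum(f, eps, branch = n, flags = flags)
}
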