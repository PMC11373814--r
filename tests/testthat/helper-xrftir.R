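# shared fixtures, built in code

testCalib <- function(...) defaultCalibration()

testMatrix <- function() defaultTissueMatrix()

# a synthetic emission line at an arbitrary energy (for fit geometry tests)
makeLine <- function(energy, element = "X", yield = 0.1, g = 0.9,
                     edge = energy + 1) {
  new("EmissionLine", element = element, transition = "Ka", energy = energy,
      fluorYield = yield, transitionProb = g, edge = edge)
}

# noiseless spectrum composed of Gaussian lines (areas in counts) on a flat
# background, on the default synthetic energy axis
composeSpectrum <- function(areas, centers, calib, background = 0,
                            offset = 0.7, gain = 0.01, n = 550,
                            liveTime = 5, poissonSeed = NULL) {
  E <- offset + gain * (0:(n - 1))
  y <- rep(background, n)
  for (i in seq_along(areas)) {
    pr <- responseProfile(centers[i], calib)
    y <- y + areas[i] * dnorm(E, pr$center, pr$sigma) * gain
  }
  if (!is.null(poissonSeed)) {
    old <- .Random.seed
    on.exit(.Random.seed <<- old)
    set.seed(poissonSeed)
    y <- rpois(n, y)
  }
  sddSpectrum(y, offset, gain, liveTime)
}

# brute-force two-sided Mann-Whitney p by enumeration of all labelings
enumMannWhitneyP <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  uOf <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  obs <- uOf(seq_len(na))
  mid <- na * nb / 2
  sel <- utils::combn(na + nb, na)
  us <- apply(sel, 2, uOf)
  mean(abs(us - mid) >= abs(obs - mid) - 1e-9)
}
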