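## Shared fixtures, all built in code.

## a single talin-like domain for ramp-mode physics checks
singleDomainConstruct <- function(k0 = 0.06, dx = 1.5, deltaLc = 40) {
  PolyproteinConstruct(list(FoldableDomain("D", 100, deltaLc, k0, dx)),
                       handleContour = 30)
}

## three domains with well-separated rupture forces, for detection studies
separatedConstruct <- function() {
  PolyproteinConstruct(list(
    FoldableDomain("A", 100, 36, 0.05, 0.9),   # ruptures ~35 pN
    FoldableDomain("B", 100, 34, 0.01, 0.5),   # ruptures ~90 pN
    FoldableDomain("C", 100, 32, 3.3e-4, 0.25) # ruptures ~215 pN
  ), handleContour = 30)
}

studyProtocol <- function(noiseSd = 0)
  PullingProtocol(forceNoiseSd = noiseSd)

## noise-matched detection settings for the 5 pN-noise study conditions
studyDetect <- list(minDrop = 7, smoothWindow = 51)

## a pure WLC force-extension trace with no foldable domains
pureWLCTrace <- function(lc = 150, lp = 0.4, n = 400, fmax = 60,
                         noiseSd = 0, seed = 1) {
  params <- WLCParams(lp, lc)
  f <- seq(0.5, fmax, length.out = n)
  x <- wlcExtension(f, params)
  if (noiseSd > 0) {
    f <- withr::with_seed(seed, f + rnorm(n, 0, noiseSd))
  }
  new("ForceExtensionTrace", time = seq_len(n) * 1e-3, piezo = x + f / 7,
      force = f, extension = x, cantileverStiffness = 7,
      groundTruth = MechanoKit:::.emptyGroundTruth())
}
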