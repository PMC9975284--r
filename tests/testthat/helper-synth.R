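# Shared fixtures: small study configurations and a memoized
# default-condition compendium so several test files can reuse one
# normalized dataset.

.cache <- new.env(parent = emptyenv())

# Small configuration for fast structural tests.
smallConfig <- function(seed = 1, ...) {
  args <- list(nStudies = 2, cancerTypesPerStudy = 2, samplesPerStudy = 60,
               nGenes = 300, kSubtypes = 4, genesPerModule = 40,
               delta = 1.5, nPairs = 60, nDrugs = 20, nCellLines = 200,
               seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(synthConfig, args)
}

# The default study conditions (4 subtypes, 150-gene modules, delta 1.5,
# 4 studies x 100 samples), normalized once per seed.
defaultCompendium <- function(seed = 11) {
  key <- paste0("comp", seed)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  cfg <- synthConfig(seed = seed)
  sim <- simulateCompendium(cfg)
  asm <- assembleCompendium(sim$tables, sim$annotations,
                            universeRule = "union")
  comp <- centerScaleWithinStrata(asm$log2, asm$annotations)
  .cache[[key]] <- list(cfg = cfg, sim = sim, comp = comp)
  .cache[[key]]
}

# The planted gene -> subtype module layout for a config (disjoint blocks
# of genesPerModule genes from the start of the universe).
moduleMapFor <- function(cfg) {
  stats::setNames(
    rep(paste0("s", seq_len(cfg$kSubtypes)), each = cfg$genesPerModule),
    sprintf("g%05d", seq_len(cfg$kSubtypes * cfg$genesPerModule)))
}

# Brute-force one-sided hypergeometric tail oracle for a 2x2 table
# (a, b; c, d): P(X >= a) by direct density summation.
hyperTailOracle <- function(a, b, c, d) {
  kmax <- min(a + b, a + c)
  if (a > kmax) return(0)
  sum(stats::dhyper(a:kmax, a + b, c + d, a + c))
}
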