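# Synthetic multi-study compendium generator with planted ground truth.
#
# Expression is simulated in log2 space: per-gene baseline + per-study and
# per-cancer-type location shifts + a subtype shift on module genes +
# i.i.d. Gaussian noise, then exponentiated to a TPM-like positive scale.
# The normalization pipeline works in SD-from-median units, so only the
# relative structure matters; no attempt is made to mimic count
# overdispersion or gene-length bias.

#' Configuration for the synthetic compendium generator
#'
#' Defaults encode the study conditions exercised throughout the test
#' suite: 4 planted subtypes, 150-gene modules shifted by 1.5 SD, 4 studies
#' of 100 samples over a 2,000-gene universe, 5% of genes missing per
#' study, a 0.4 metastasis subtype-switch rate, and subtype-enriched copy
#' gains at 8-fold odds.
#'
#' @param nStudies Number of studies in the compendium.
#' @param cancerTypesPerStudy Cancer types represented within each study
#'   (a shared pool of this size is used by all studies).
#' @param samplesPerStudy Samples per study.
#' @param nGenes Size of the gene universe.
#' @param kSubtypes Number of planted subtypes.
#' @param genesPerModule Genes per subtype module (modules are disjoint;
#'   \code{kSubtypes * genesPerModule <= nGenes}).
#' @param delta Log2-space shift (in noise-SD units, \code{noiseSd = 1})
#'   applied to a subtype's module genes in that subtype's samples.
#' @param studyShiftSd,tissueShiftSd SDs of per-gene location batch effects
#'   for study and cancer type.
#' @param missingGeneFraction Fraction of genes absent per study (distinct
#'   uniform draws per study).
#' @param switchRate Probability a metastasis's subtype differs from its
#'   paired primary's.
#' @param ploidyWeights Named weights over baseline ploidies 2, 3, 4.
#' @param gainOdds Odds multiplier for copy gains of a subtype's module
#'   genes within that subtype.
#' @param baseGainRate Background per-gene copy-gain probability.
#' @param drugEffect Ln-IC50 decrease for planted sensitive (subtype, drug)
#'   pairs.
#' @param noiseSd Log2 expression noise SD.
#' @param multiSamplePatientFraction Fraction of patients contributing 2-5
#'   tumors (needed to exercise plurality statistics).
#' @param intraPatientSwitchRate Probability a patient's additional tumor
#'   takes a different subtype from the patient's main subtype.
#' @param nPairs Metastasis/primary pairs in the paired cohort.
#' @param nMutGenes Size of the mutation gene panel.
#' @param baseMutationRate Background per-gene mutation probability.
#' @param mutationRateMultiplier Rate multiplier for planted
#'   (gene, subtype) mutation enrichments.
#' @param nDrugs Number of drugs screened.
#' @param nCellLines Number of cell lines.
#' @param sensitiveDrugsPerSubtype Planted sensitive drugs per subtype.
#' @param seed Integer RNG seed; all generators derive named child seeds
#'   from it.
#' @return A validated list of class \code{SynthConfig}.
#' @export
synthConfig <- function(nStudies = 4, cancerTypesPerStudy = 2,
                        samplesPerStudy = 100, nGenes = 2000,
                        kSubtypes = 4, genesPerModule = 150, delta = 1.5,
                        studyShiftSd = 0.5, tissueShiftSd = 0.5,
                        missingGeneFraction = 0.05, switchRate = 0.4,
                        ploidyWeights = c("2" = 0.7, "3" = 0.2, "4" = 0.1),
                        gainOdds = 8, baseGainRate = 0.05,
                        drugEffect = 1.0, noiseSd = 1,
                        multiSamplePatientFraction = 0.3,
                        intraPatientSwitchRate = 0,
                        nPairs = 300, nMutGenes = 100,
                        baseMutationRate = 0.08, mutationRateMultiplier = 5,
                        nDrugs = 50, nCellLines = 600,
                        sensitiveDrugsPerSubtype = 3, seed = 1) {
  cfg <- list(nStudies = as.integer(nStudies),
              cancerTypesPerStudy = as.integer(cancerTypesPerStudy),
              samplesPerStudy = as.integer(samplesPerStudy),
              nGenes = as.integer(nGenes), kSubtypes = as.integer(kSubtypes),
              genesPerModule = as.integer(genesPerModule), delta = delta,
              studyShiftSd = studyShiftSd, tissueShiftSd = tissueShiftSd,
              missingGeneFraction = missingGeneFraction,
              switchRate = switchRate, ploidyWeights = ploidyWeights,
              gainOdds = gainOdds, baseGainRate = baseGainRate,
              drugEffect = drugEffect, noiseSd = noiseSd,
              multiSamplePatientFraction = multiSamplePatientFraction,
              intraPatientSwitchRate = intraPatientSwitchRate,
              nPairs = as.integer(nPairs), nMutGenes = as.integer(nMutGenes),
              baseMutationRate = baseMutationRate,
              mutationRateMultiplier = mutationRateMultiplier,
              nDrugs = as.integer(nDrugs), nCellLines = as.integer(nCellLines),
              sensitiveDrugsPerSubtype = as.integer(sensitiveDrugsPerSubtype),
              seed = as.integer(seed))
  counts <- c("nStudies", "cancerTypesPerStudy", "samplesPerStudy",
              "nGenes", "kSubtypes", "genesPerModule", "nPairs",
              "nMutGenes", "nDrugs", "nCellLines")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0)
      stop("SynthConfig: ", f, " must be a positive count")
  rates <- c("missingGeneFraction", "switchRate", "baseGainRate",
             "baseMutationRate", "multiSamplePatientFraction",
             "intraPatientSwitchRate")
  for (f in rates)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("SynthConfig: ", f, " must lie in [0,1]")
  if (cfg$kSubtypes * cfg$genesPerModule > cfg$nGenes)
    stop("SynthConfig: kSubtypes * genesPerModule exceeds nGenes")
  if (any(cfg$ploidyWeights < 0) || sum(cfg$ploidyWeights) <= 0)
    stop("SynthConfig: invalid ploidyWeights")
  if (!setequal(names(cfg$ploidyWeights), c("2", "3", "4")))
    stop("SynthConfig: ploidyWeights must be named '2','3','4'")
  class(cfg) <- "SynthConfig"
  cfg
}

geneIds <- function(n) sprintf("g%05d", seq_len(n))

subtypeIds <- function(k) paste0("s", seq_len(k))

# gene -> subtype map for the planted disjoint modules (first k*m genes)
moduleMap <- function(cfg) {
  genes <- geneIds(cfg$nGenes)
  mods <- rep(subtypeIds(cfg$kSubtypes), each = cfg$genesPerModule)
  stats::setNames(mods, genes[seq_along(mods)])
}

# Per-gene log2 baselines, drawn once per config seed so every generated
# table (compendium, pairs, cell lines) shares the same gene landscape.
geneBaselines <- function(cfg) {
  withSeed(childSeed(cfg$seed, "baselines"),
           stats::setNames(stats::rnorm(cfg$nGenes, mean = 6, sd = 1),
                           geneIds(cfg$nGenes)))
}

tissueShifts <- function(cfg) {
  cts <- paste0("ct", seq_len(cfg$cancerTypesPerStudy))
  withSeed(childSeed(cfg$seed, "tissue"), {
    m <- matrix(stats::rnorm(cfg$nGenes * length(cts), 0, cfg$tissueShiftSd),
                nrow = cfg$nGenes, dimnames = list(geneIds(cfg$nGenes), cts))
    m
  })
}

# Simulate one block of samples: log2 values then 2^x (TPM-like scale).
simulateBlock <- function(cfg, subtypes, cancerTypes, studyShift, tshift,
                          baselines, sampleIds) {
  genes <- names(baselines)
  mods <- moduleMap(cfg)
  n <- length(subtypes)
  x <- matrix(stats::rnorm(length(genes) * n, 0, cfg$noiseSd),
              nrow = length(genes), dimnames = list(genes, sampleIds))
  x <- x + baselines + studyShift
  x <- x + tshift[, cancerTypes, drop = FALSE]
  modGenes <- names(mods)
  shift <- outer(mods[modGenes], subtypes, function(m, s) ifelse(m == s, cfg$delta, 0))
  x[modGenes, ] <- x[modGenes, ] + shift
  2^x
}

# Patient structure for one study: a fraction of patients contribute 2-5
# tumors sharing one subtype (up to intra-patient switching).
drawPatients <- function(cfg, nSamples, prefix) {
  pats <- character(0); subs <- character(0)
  labels <- subtypeIds(cfg$kSubtypes)
  i <- 0
  while (length(pats) < nSamples) {
    i <- i + 1
    pid <- sprintf("%s_p%04d", prefix, i)
    k <- if (stats::runif(1) < cfg$multiSamplePatientFraction)
      sample(2:5, 1) else 1L
    k <- min(k, nSamples - length(pats))
    base <- sample(labels, 1)
    st <- rep(base, k)
    if (cfg$intraPatientSwitchRate > 0 && k > 1) {
      sw <- stats::runif(k - 1) < cfg$intraPatientSwitchRate
      if (any(sw) && cfg$kSubtypes > 1)
        st[which(sw) + 1] <- vapply(which(sw), function(j)
          sample(setdiff(labels, base), 1), character(1))
    }
    pats <- c(pats, rep(pid, k)); subs <- c(subs, st)
  }
  list(patient = pats, subtype = subs)
}

#' Generate a multi-study synthetic expression compendium
#'
#' Produces per-study gene x sample tables on a TPM-like positive scale
#' with planted subtype modules, study- and tissue-level batch effects and
#' per-study missing genes, plus sample annotations and the ground truth.
#'
#' @param cfg A [synthConfig()].
#' @return List with \code{tables} (named list of per-study matrices, rows
#'   already restricted to each study's present genes), \code{annotations}
#'   (data.frame with sample_id, patient_id, study_id, cancer_type,
#'   sample_class, biopsy_site) and \code{truth} (list with
#'   \code{subtype} sample map, \code{modules} gene map, \code{gains} and
#'   \code{drugs} planted-flag tables filled by the downstream generators).
#' @export
simulateCompendium <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  baselines <- geneBaselines(cfg)
  tshift <- tissueShifts(cfg)
  cts <- colnames(tshift)
  genes <- names(baselines)
  withSeed(childSeed(cfg$seed, "compendium"), {
    tables <- list(); ann <- list(); subtypeMap <- character(0)
    for (s in seq_len(cfg$nStudies)) {
      sid <- sprintf("study%02d", s)
      studyShift <- stats::rnorm(cfg$nGenes, 0, cfg$studyShiftSd)
      ps <- drawPatients(cfg, cfg$samplesPerStudy, sid)
      sampleIds <- sprintf("%s_t%04d", sid, seq_len(cfg$samplesPerStudy))
      sampleCt <- sample(cts, cfg$samplesPerStudy, replace = TRUE)
      # samples of one patient share a cancer type
      sampleCt <- stats::ave(sampleCt, ps$patient, FUN = function(v) v[1])
      x <- simulateBlock(cfg, ps$subtype, sampleCt, studyShift, tshift,
                         baselines, sampleIds)
      nMiss <- round(cfg$missingGeneFraction * cfg$nGenes)
      if (nMiss > 0) x <- x[-sample(cfg$nGenes, nMiss), , drop = FALSE]
      tables[[sid]] <- x
      ann[[sid]] <- data.frame(sample_id = sampleIds, patient_id = ps$patient,
                               study_id = sid, cancer_type = sampleCt,
                               sample_class = "PDX",
                               biopsy_site = NA_character_)
      subtypeMap <- c(subtypeMap, stats::setNames(ps$subtype, sampleIds))
    }
    list(tables = tables, annotations = do.call(rbind, ann),
         truth = list(subtype = subtypeMap, modules = moduleMap(cfg),
                      pairs = NULL, gains = NULL, mutations = NULL,
                      drugs = NULL))
  })
}

#' Generate a paired primary/metastasis cohort
#'
#' Each pair shares a patient; the metastasis subtype equals the primary's
#' with probability \code{1 - switchRate}, otherwise it is drawn uniformly
#' from the remaining subtypes. Expression follows the compendium model
#' (two paired studies).
#'
#' @param cfg A [synthConfig()].
#' @param truth Optional ground-truth list to extend.
#' @return List with \code{met} and \code{primary} linear-scale matrices
#'   (columns aligned pair-for-pair), \code{pairs} annotation data.frame
#'   (met_id, primary_id, patient_id, study_id, cancer_type, metSubtype,
#'   primarySubtype) and updated \code{truth}.
#' @export
simulatePairedCohort <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "SynthConfig"))
  baselines <- geneBaselines(cfg)
  tshift <- tissueShifts(cfg)
  labels <- subtypeIds(cfg$kSubtypes)
  withSeed(childSeed(cfg$seed, "paired"), {
    n <- cfg$nPairs
    study <- sprintf("paired%02d", 1 + (seq_len(n) %% 2))
    ct <- sample(colnames(tshift), n, replace = TRUE)
    priSub <- sample(labels, n, replace = TRUE)
    switched <- stats::runif(n) < cfg$switchRate
    metSub <- priSub
    if (cfg$kSubtypes > 1 && any(switched))
      metSub[switched] <- vapply(priSub[switched], function(p)
        sample(setdiff(labels, p), 1), character(1))
    patient <- sprintf("pair_p%04d", seq_len(n))
    metIds <- sprintf("pair_m%04d", seq_len(n))
    priIds <- sprintf("pair_b%04d", seq_len(n))
    studyShift <- stats::setNames(lapply(unique(study), function(s)
      stats::rnorm(cfg$nGenes, 0, cfg$studyShiftSd)), unique(study))
    met <- matrix(NA_real_, cfg$nGenes, n,
                  dimnames = list(names(baselines), metIds))
    pri <- matrix(NA_real_, cfg$nGenes, n,
                  dimnames = list(names(baselines), priIds))
    for (s in unique(study)) {
      i <- which(study == s)
      met[, i] <- simulateBlock(cfg, metSub[i], ct[i], studyShift[[s]],
                                tshift, baselines, metIds[i])
      pri[, i] <- simulateBlock(cfg, priSub[i], ct[i], studyShift[[s]],
                                tshift, baselines, priIds[i])
    }
    pairs <- data.frame(met_id = metIds, primary_id = priIds,
                        patient_id = patient, study_id = study,
                        cancer_type = ct, metSubtype = metSub,
                        primarySubtype = priSub)
    if (is.null(truth)) truth <- list(modules = moduleMap(cfg))
    truth$pairs <- pairs
    truth$subtype <- c(truth$subtype,
                       stats::setNames(metSub, metIds),
                       stats::setNames(priSub, priIds))
    list(met = met, primary = pri, pairs = pairs, truth = truth)
  })
}

#' Generate integer gene copy-number data with subtype-enriched gains
#'
#' Baseline copy equals the sample's ploidy (drawn from
#' \code{ploidyWeights}) for all genes; each subtype's module genes receive
#' +1/+2 gains at \code{gainOdds}-fold odds over \code{baseGainRate} in
#' that subtype's samples.
#'
#' @param cfg A [synthConfig()].
#' @param truth Ground truth holding the sample subtype map.
#' @param sampleIds Samples to simulate (default: all in
#'   \code{truth$subtype}).
#' @return List with \code{copies} (integer gene x sample matrix) and
#'   updated \code{truth} (\code{gains}: data.frame gene/subtype of planted
#'   enrichments).
#' @export
simulateCopyNumber <- function(cfg, truth, sampleIds = names(truth$subtype)) {
  stopifnot(inherits(cfg, "SynthConfig"))
  sub <- truth$subtype[sampleIds]
  if (anyNA(sub)) stop("samples without subtype in truth")
  genes <- geneIds(cfg$nGenes)
  mods <- truth$modules
  withSeed(childSeed(cfg$seed, "copynumber"), {
    n <- length(sampleIds)
    ploidy <- sample(as.integer(names(cfg$ploidyWeights)), n, replace = TRUE,
                     prob = cfg$ploidyWeights)
    copies <- matrix(rep(ploidy, each = cfg$nGenes), nrow = cfg$nGenes,
                     dimnames = list(genes, sampleIds))
    p0 <- cfg$baseGainRate
    pEnr <- if (p0 > 0) {
      o <- p0 / (1 - p0) * cfg$gainOdds
      o / (1 + o)
    } else 0
    pMat <- matrix(p0, cfg$nGenes, n, dimnames = list(genes, sampleIds))
    if (length(mods))
      pMat[names(mods), ] <- ifelse(
        outer(mods, sub, "=="), pEnr, p0)[names(mods), ]
    gained <- matrix(stats::runif(cfg$nGenes * n) < pMat, cfg$nGenes, n)
    amount <- matrix(sample(c(1L, 2L), cfg$nGenes * n, replace = TRUE,
                            prob = c(0.7, 0.3)), cfg$nGenes, n)
    copies <- copies + gained * amount
    truth$gains <- if (length(mods))
      data.frame(gene = names(mods), subtype = unname(mods)) else
      data.frame(gene = character(0), subtype = character(0))
    list(copies = copies, ploidy = stats::setNames(ploidy, sampleIds),
         truth = truth)
  })
}

#' Generate a binary somatic-mutation table with planted enrichments
#'
#' A panel of \code{nMutGenes} genes is mutated Bernoulli at
#' \code{baseMutationRate}; the first gene of each subtype's planted set
#' carries \code{mutationRateMultiplier} times the base rate in that
#' subtype's samples.
#'
#' @inheritParams simulateCopyNumber
#' @return List with \code{mutations} (0/1 gene x sample matrix) and
#'   updated \code{truth} (\code{mutations}: planted gene/subtype table).
#' @export
simulateMutations <- function(cfg, truth, sampleIds = names(truth$subtype)) {
  stopifnot(inherits(cfg, "SynthConfig"))
  sub <- truth$subtype[sampleIds]
  panel <- sprintf("mut%03d", seq_len(cfg$nMutGenes))
  labels <- subtypeIds(cfg$kSubtypes)
  nPlant <- min(cfg$kSubtypes, cfg$nMutGenes)
  planted <- data.frame(gene = panel[seq_len(nPlant)],
                        subtype = labels[seq_len(nPlant)])
  withSeed(childSeed(cfg$seed, "mutations"), {
    n <- length(sampleIds)
    rate <- matrix(cfg$baseMutationRate, cfg$nMutGenes, n,
                   dimnames = list(panel, sampleIds))
    for (i in seq_len(nrow(planted)))
      rate[planted$gene[i], sub == planted$subtype[i]] <-
        min(1, cfg$baseMutationRate * cfg$mutationRateMultiplier)
    mut <- matrix(as.integer(stats::runif(cfg$nMutGenes * n) < rate),
                  cfg$nMutGenes, n, dimnames = dimnames(rate))
    truth$mutations <- planted
    list(mutations = mut, truth = truth)
  })
}

#' Generate cell-line ln IC50 drug response and matching expression
#'
#' Cell lines get uniform subtypes and compendium-model expression (single
#' cell-line study, no missing genes). Each planted sensitive
#' (subtype, drug) pair shifts ln IC50 down by \code{drugEffect}; noise is
#' Gaussian with SD \code{noiseSd}.
#'
#' @param cfg A [synthConfig()].
#' @param truth Optional ground-truth list to extend.
#' @return List with \code{ic50} (drug x cell-line matrix),
#'   \code{expression} (linear-scale gene x cell-line matrix),
#'   \code{annotations}, \code{lineSubtype}, and updated \code{truth}
#'   (\code{drugs}: planted drug/subtype pairs).
#' @export
simulateDrugResponse <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "SynthConfig"))
  baselines <- geneBaselines(cfg)
  tshift <- tissueShifts(cfg)
  labels <- subtypeIds(cfg$kSubtypes)
  drugs <- sprintf("drug%03d", seq_len(cfg$nDrugs))
  nPlant <- min(cfg$sensitiveDrugsPerSubtype * cfg$kSubtypes, cfg$nDrugs)
  planted <- data.frame(drug = drugs[seq_len(nPlant)],
                        subtype = rep(labels, length.out = nPlant))
  withSeed(childSeed(cfg$seed, "drugs"), {
    n <- cfg$nCellLines
    lineIds <- sprintf("cl%04d", seq_len(n))
    sub <- sample(labels, n, replace = TRUE)
    ct <- sample(colnames(tshift), n, replace = TRUE)
    studyShift <- stats::rnorm(cfg$nGenes, 0, cfg$studyShiftSd)
    expr <- simulateBlock(cfg, sub, ct, studyShift, tshift, baselines,
                          lineIds)
    base <- stats::rnorm(cfg$nDrugs, 2, 1)
    ic50 <- matrix(base + stats::rnorm(cfg$nDrugs * n, 0, cfg$noiseSd),
                   cfg$nDrugs, n, dimnames = list(drugs, lineIds))
    for (i in seq_len(nrow(planted)))
      ic50[planted$drug[i], sub == planted$subtype[i]] <-
        ic50[planted$drug[i], sub == planted$subtype[i]] - cfg$drugEffect
    ann <- data.frame(sample_id = lineIds, patient_id = lineIds,
                      study_id = "celllines", cancer_type = ct,
                      sample_class = "cell_line",
                      biopsy_site = NA_character_)
    if (is.null(truth)) truth <- list(modules = moduleMap(cfg))
    truth$drugs <- planted
    truth$subtype <- c(truth$subtype, stats::setNames(sub, lineIds))
    list(ic50 = ic50, expression = expr, annotations = ann,
         lineSubtype = stats::setNames(sub, lineIds), truth = truth)
  })
}

#' Generate reference differential profiles and TF-target/annotation sets
#'
#' One reference profile per subtype (weight \code{delta} on its module
#' genes, 0 elsewhere), plus per-subtype TF-target and annotation gene sets
#' overlapping the planted modules at the requested fidelity.
#'
#' @param cfg A [synthConfig()].
#' @param truth Ground truth holding the gene module map.
#' @param fidelity Fraction of each set drawn from the subtype's module
#'   genes (remainder drawn uniformly from non-module genes).
#' @return List with \code{referenceProfiles} (gene x subtype matrix),
#'   \code{tfSets} and \code{annotationSets} (named lists of gene
#'   vectors), and \code{tfGenes} (the planted TF gene per subtype). Each
#'   TF set is named by its TF gene id -- the first module gene of the
#'   subtype -- so the TF's own expression shift is testable.
#' @export
simulateReferences <- function(cfg, truth, fidelity = 1) {
  stopifnot(inherits(cfg, "SynthConfig"), fidelity >= 0, fidelity <= 1)
  genes <- geneIds(cfg$nGenes)
  mods <- truth$modules
  labels <- subtypeIds(cfg$kSubtypes)
  refs <- vapply(labels, function(k) {
    w <- numeric(cfg$nGenes)
    w[match(names(mods)[mods == k], genes)] <- cfg$delta
    w
  }, numeric(cfg$nGenes))
  rownames(refs) <- genes
  withSeed(childSeed(cfg$seed, "references"), {
    makeSet <- function(k) {
      mg <- names(mods)[mods == k]
      other <- setdiff(genes, names(mods))
      nIn <- round(fidelity * length(mg))
      c(if (nIn > 0) sample(mg, nIn) else character(0),
        sample(other, length(mg) - nIn))
    }
    tfGenes <- vapply(labels, function(k) names(mods)[mods == k][1],
                      character(1))
    tfSets <- stats::setNames(lapply(labels, makeSet), tfGenes)
    annSets <- stats::setNames(lapply(labels, makeSet),
                               paste0("term_", labels))
    list(referenceProfiles = refs, tfSets = tfSets,
         annotationSets = annSets, tfGenes = tfGenes)
  })
}
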