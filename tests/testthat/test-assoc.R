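test_that("Welch differential expression matches closed-form and t.test", {
  x <- matrix(c(1.2, 3.1, 2.4, 0.7, 5.0, 1.6,
                2.0, 2.5, 1.0, 0.2, 4.1, 3.3,
                0.5, 4.0, 3.3, 1.9, 2.2, 0.8,
                1.1, 1.8, 2.6, 3.0, 0.9, 2.2) , 4, 6, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  labels <- c("a", "a", "a", "b", "b", "b")
  de <- differentialExpression(x, labels, subtype = "a")
  for (g in rownames(x)) {
    tt <- t.test(x[g, 1:3], x[g, 4:6])
    row <- de[de$gene == g, ]
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(row$p, tt$p.value, tolerance = 1e-12)
    expect_equal(row$mean_diff,
                 unname(tt$estimate[1] - tt$estimate[2]), tolerance = 1e-12)
  }
  # identical groups: t = 0, p = 1
  same <- matrix(rep(c(1, 2, 1, 2), 2), 1, 8,
                 dimnames = list("g", paste0("s", 1:8)))
  deS <- differentialExpression(same, rep(c("a", "b"), each = 4),
                                subtype = "a")
  expect_equal(deS$t, 0); expect_equal(deS$p, 1)
  # separated constants: flagged extreme
  sep <- matrix(c(2, 2, 2, 0, 0, 0), 1, 6,
                dimnames = list("g", paste0("s", 1:6)))
  deE <- differentialExpression(sep, rep(c("a", "b"), each = 3), "a")
  expect_true(is.infinite(deE$t) && deE$t > 0)
  expect_equal(deE$p, 0)
  expect_true(deE$highest_in_subtype)
})

test_that("highest-in-subtype flag requires the top mean across subtypes", {
  x <- rbind(g1 = c(3, 3.1, 3, 2, 2.1, 2, 1, 1.1, 1),
             g2 = c(1, 1.1, 1, 3, 3.1, 3, 2, 2.1, 2))
  colnames(x) <- paste0("s", 1:9)
  labels <- rep(c("a", "b", "c"), each = 3)
  de <- differentialExpression(x, labels)
  expect_true(de$highest_in_subtype[de$gene == "g1" & de$subtype == "a"])
  expect_false(de$highest_in_subtype[de$gene == "g1" & de$subtype == "b"])
  expect_true(de$highest_in_subtype[de$gene == "g2" & de$subtype == "b"])
})

test_that("paired differential matches the hand-computed one-sample t", {
  d <- matrix(c(2, -1, 3, 0, 1), 1, 5,
              dimnames = list("g", paste0("m", 1:5)))
  pd <- pairedDifferential(d)
  expect_equal(pd$t, 1 / (sd(c(2, -1, 3, 0, 1)) / sqrt(5)), tolerance = 1e-12)
  expect_equal(pd$t, 1.4142, tolerance = 1e-4)
  expect_equal(pd$p, t.test(c(2, -1, 3, 0, 1))$p.value, tolerance = 1e-12)
  zero <- matrix(0, 1, 4, dimnames = list("g", paste0("m", 1:4)))
  pdZ <- pairedDifferential(zero)
  expect_equal(pdZ$t, 0); expect_equal(pdZ$p, 1)
  ones <- matrix(1, 1, 4, dimnames = list("g", paste0("m", 1:4)))
  pdO <- pairedDifferential(ones)
  expect_true(is.infinite(pdO$t))
  expect_equal(pdO$p, 0)
  expect_error(pairedDifferential(d[, 1:2, drop = FALSE]), ">= 3 pairs")
})

test_that("t-test p-values are uniform under an exchangeable null", {
  set.seed(77)
  x <- matrix(rnorm(2000 * 40), 2000, 40,
              dimnames = list(sprintf("g%04d", 1:2000), paste0("s", 1:40)))
  labels <- rep(c("a", "b"), each = 20)
  de <- differentialExpression(x, labels, "a")
  expect_gt(ks.test(de$p, "punif")$p.value, 0.01)
  pd <- pairedDifferential(x[, 1:20])
  expect_gt(ks.test(pd$p, "punif")$p.value, 0.01)
})

test_that("gene-set overlap matches the brute-force hypergeometric tail", {
  U <- sprintf("u%03d", 1:100)
  A <- U[1:20]; B <- U[11:30]  # |A n B| = 10
  ov <- geneSetOverlap(A, B, U, method = "fisher")
  expect_equal(ov$both, 10)
  oracle <- sum(dhyper(10:20, 20, 80, 20))
  expect_equal(ov$p, oracle, tolerance = 1e-12)
  # A = B: maximal overlap, minimal p
  ovAA <- geneSetOverlap(A, A, U, method = "fisher")
  expect_equal(ovAA$both, 20)
  expect_equal(ovAA$p, 1 / choose(100, 20), tolerance = 1e-9)
  # disjoint sets covering the universe: p = 1
  ovD <- geneSetOverlap(U[1:50], U[51:100], U, method = "fisher")
  expect_equal(ovD$p, 1)
  expect_error(geneSetOverlap(A, B, character(0)), "empty universe")
})

test_that("orthogonal overlap matrix is diagonal-dominant on planted data", {
  set.seed(9)
  U <- sprintf("u%04d", 1:2000)
  modules <- split(U[1:400], rep(paste0("s", 1:4), each = 100))
  noisy <- function(s) c(sample(s, 80), sample(setdiff(U, s), 40))
  fam1 <- lapply(modules, noisy)
  fam2 <- lapply(modules, noisy)
  om <- orthogonalOverlapMatrix(fam1, fam2, U)
  expect_lt(max(diag(om$p)), 1e-6)
  expect_lt(max(diag(om$p)), min(om$p[row(om$p) != col(om$p)]))
  expect_setequal(om$consensus,
                  unique(unlist(Map(intersect, fam1, fam2))))
  # identical families: consensus is the union of the sets
  omI <- orthogonalOverlapMatrix(fam1, fam1, U)
  expect_setequal(omI$consensus, unlist(fam1))
  # label shuffling kills every diagonal cell
  shuf <- lapply(fam2, function(s) sample(U, length(s)))
  omS <- orthogonalOverlapMatrix(fam1, shuf, U)
  expect_gt(min(diag(omS$p)), 1e-6)
  expect_length(omS$consensus, 0)
})

test_that("signature scoring is a shared-gene Pearson correlation", {
  set.seed(12)
  genes <- sprintf("g%03d", 1:100)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(genes, c("a", "b", "c")))
  # reference equal to a sample's profile scores 1 there
  ss <- signatureScore(x, setNames(x[, "b"], genes), "ref")
  expect_equal(ss$score[ss$sample_id == "b"], 1)
  # residualized (orthogonal) reference scores 0
  v <- x[, "a"]
  ref <- rnorm(100)
  orth <- ref - mean(ref) -
    cov(ref, v) / var(v) * (v - mean(v))
  sO <- signatureScore(x, setNames(orth, genes), "orth")
  expect_equal(sO$score[sO$sample_id == "a"], 0, tolerance = 1e-10)
  # invariant to positive rescaling of the reference
  s1 <- signatureScore(x, setNames(ref, genes))
  s2 <- signatureScore(x, setNames(ref * 4.2, genes))
  expect_equal(s1$score, s2$score)
  expect_error(signatureScore(x[1:10, ], setNames(ref[1:10], genes[1:10])),
               "floor is 30")
})

test_that("TF enrichment demands overlap and expression in both families", {
  env <- defaultCompendium(11)
  x <- sduMatrix(env$comp)
  truth <- env$sim$truth$subtype[colnames(x)]
  refs <- simulateReferences(env$cfg, env$sim$truth, fidelity = 1)
  de <- differentialExpression(env$comp, truth)
  sets <- lapply(split(de, de$subtype),
                 function(d) d$gene[d$p < 0.01 & d$highest_in_subtype])
  tfr <- tfEnrichment(refs$tfSets, sets, sets, x, x, truth, truth)
  hits <- tfr[tfr$passes, ]
  # each planted TF passes exactly in its own subtype, direction up
  expect_equal(nrow(hits), 4)
  expect_setequal(hits$tf, names(refs$tfSets))
  expect_true(all(hits$direction == "up"))
  plantedSub <- env$sim$truth$modules[hits$tf]
  expect_equal(unname(plantedSub), hits$subtype)
  # a TF with targets disjoint from every DE set fails
  cold <- list(setdiff(rownames(x), unlist(sets))[1:150])
  names(cold) <- hits$tf[1]
  tfrC <- tfEnrichment(cold, sets, sets, x, x, truth, truth)
  expect_false(any(tfrC$passes))
  # raising the overlap cutoff to 1 passes any overlapping expressed TF
  tfrLoose <- tfEnrichment(refs$tfSets, sets, sets, x, x, truth, truth,
                           overlapCut = 1.01, exprCut = 1.01)
  expect_gte(sum(tfrLoose$passes), sum(tfr$passes))
})

test_that("annotation enrichment sorts terms by a Fisher oracle", {
  U <- sprintf("u%03d", 1:60)
  gs <- U[1:12]
  ann <- list(hit = gs, part = U[10:20], miss = U[59])
  res <- annotationEnrichment(gs, ann, U)
  expect_equal(res$term[1], "hit")
  expect_equal(res$p[res$term == "hit"],
               hyperTailOracle(12, 0, 0, 48), tolerance = 1e-12)
  expect_equal(res$p[res$term == "miss"], 1)
  partRow <- res[res$term == "part", ]
  expect_equal(partRow$p,
               hyperTailOracle(partRow$overlap, 12 - partRow$overlap,
                               11 - partRow$overlap,
                               60 - 12 - 11 + partRow$overlap),
               tolerance = 1e-12)
  expect_error(annotationEnrichment(gs, list(), U), "empty")
})

test_that("IC50 merging averages shared cells and unions the rest", {
  a <- matrix(1, 1, 1, dimnames = list("d1", "c1"))
  b <- matrix(3, 1, 1, dimnames = list("d1", "c1"))
  expect_equal(mergeIC50(a, b)["d1", "c1"], 2)
  c2 <- matrix(5, 1, 1, dimnames = list("d2", "c2"))
  m <- mergeIC50(a, c2)
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["d1", "c1"], 1); expect_equal(m["d2", "c2"], 5)
  expect_true(is.na(m["d1", "c2"]))
  expect_equal(mergeIC50(a, c2), mergeIC50(c2, a))
})

test_that("drug association is calibrated under the null and flags tiny groups", {
  set.seed(15)
  ic50 <- matrix(rnorm(500 * 80), 500, 80,
                 dimnames = list(sprintf("d%03d", 1:500),
                                 sprintf("c%02d", 1:80)))
  labels <- rep(paste0("s", 1:4), each = 20)
  da <- drugResponseAssociation(ic50, labels)
  expect_gt(ks.test(da$p, "punif")$p.value, 0.01)
  # a drug measured in only 2 in-group lines is skipped with a flag
  ic2 <- ic50[1:3, , drop = FALSE]
  ic2["d001", labels == "s1"] <- NA
  ic2["d001", which(labels == "s1")[1:2]] <- 1
  da2 <- drugResponseAssociation(ic2, labels)
  expect_true(da2$skipped[da2$drug == "d001" & da2$subtype == "s1"])
  expect_true(is.na(da2$p[da2$drug == "d001" & da2$subtype == "s1"]))
})

test_that("q-value estimation tracks the planted null proportion", {
  set.seed(44)
  p <- c(runif(1800), rbeta(200, 0.05, 1))
  q <- estimateQValues(p)
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # strong signals keep small q; pure nulls do not
  expect_lt(min(q), 0.01)
  expect_gt(max(q), 0.5)
})
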