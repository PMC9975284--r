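test_that("TPM conversion matches the hand-computed rate formula", {
  m <- matrix(c(5, 7), 1, 2, dimnames = list("a", c("x", "y")))
  expect_true(all(countsToTPM(m, c(a = 500)) == 1e6))
  m2 <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "x"))
  expect_equal(unname(countsToTPM(m2, c(a = 1000, b = 1000))[, 1]),
               c(5e5, 5e5))
  # twice the counts over twice the length is the same rate
  m3 <- matrix(c(20, 10), 2, 1, dimnames = list(c("a", "b"), "x"))
  expect_equal(unname(countsToTPM(m3, c(a = 2000, b = 1000))[, 1]),
               c(5e5, 5e5))
  expect_equal(colSums(countsToTPM(matrix(rpois(50, 20), 10, 5,
                                          dimnames = list(letters[1:10],
                                                          paste0("s", 1:5))),
                                   setNames(rep(1000, 10), letters[1:10]))),
               rep(1e6, 5), ignore_attr = TRUE, tolerance = 1e-9)
  expect_error(countsToTPM(m2, c(a = 1000)), "\\bb\\b")
})

test_that("quantile normalization equalizes columns to per-rank means", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  qn <- quantileNormalizeMatrix(m)
  expect_equal(qn[, 1], c(2.5, 3.5, 4.5), ignore_attr = TRUE)
  expect_equal(qn[, 2], c(2.5, 3.5, 4.5), ignore_attr = TRUE)
  same <- matrix(c(3, 1, 2, 3, 1, 2), 3, 2)
  expect_equal(quantileNormalizeMatrix(same), same, ignore_attr = TRUE)
  # row-permutation equivariance
  set.seed(1)
  x <- matrix(rnorm(40), 10, 4)
  p <- sample(10)
  expect_equal(quantileNormalizeMatrix(x)[p, ],
               quantileNormalizeMatrix(x[p, ]), ignore_attr = TRUE)
  xna <- x; xna[, 2] <- NA
  expect_error(quantileNormalizeMatrix(xna), "all-missing")
  expect_error(quantileNormalizeMatrix(x[, 1, drop = FALSE]), ">= 2")
})

test_that("feature collapse keeps the max-SD feature with lexicographic ties", {
  x <- matrix(c(1, 1, 1, 5, 2, 8), 3, 2, byrow = TRUE,
              dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
  map <- c(f1 = "gA", f2 = "gA", f3 = "gB")
  out <- collapseFeatures(x, map, isLog2 = TRUE)
  # SDs: f1 = 0, f2 = sd(c(1,5)) = 2.83 -> f2 kept for gA
  expect_equal(sqrt(c(0, 8, 18)),
               apply(x, 1, sd), ignore_attr = TRUE)
  expect_equal(out["gA", ], x["f2", ], ignore_attr = TRUE)
  expect_equal(out["gB", ], x["f3", ], ignore_attr = TRUE)
  # exact tie -> smallest feature id
  tie <- matrix(c(1, 3, 1, 3), 2, 2, byrow = TRUE,
                dimnames = list(c("fB", "fA"), c("s1", "s2")))
  outT <- collapseFeatures(tie, c(fB = "g", fA = "g"), isLog2 = TRUE)
  expect_equal(rownames(outT), "g")
  expect_identical(unname(outT["g", ]), unname(tie["fA", ]))
  # single feature per gene is the identity (values untouched)
  one <- collapseFeatures(x[3, , drop = FALSE], map, isLog2 = TRUE)
  expect_identical(unname(one), unname(x[3, , drop = FALSE]))
})

test_that("compendium assembly applies universe rules and log2 transform", {
  t1 <- matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), c("x1", "x2")))
  t2 <- matrix(3, 3, 2, dimnames = list(c("B", "C", "D"), c("y1", "y2")))
  ann <- data.frame(sample_id = c("x1", "x2", "y1", "y2"),
                    patient_id = 1:4, study_id = rep(c("s1", "s2"), each = 2),
                    cancer_type = "ct", sample_class = "PDX")
  asmI <- assembleCompendium(list(s1 = t1, s2 = t2), ann, "intersection")
  expect_equal(rownames(asmI$log2), c("B", "C"))
  asmU <- assembleCompendium(list(s1 = t1, s2 = t2), ann, "union")
  expect_equal(rownames(asmU$log2), c("A", "B", "C", "D"))
  expect_true(all(is.na(asmU$log2["D", c("x1", "x2")])))
  expect_equal(asmU$log2["A", "x1"], log2(1 + 1))
  one <- assembleCompendium(list(s1 = t1), ann[1:2, ], "intersection")
  expect_setequal(rownames(one$log2), rownames(t1))
  expect_error(assembleCompendium(list(s1 = t1, s2 = t2), ann[1:2, ],
                                  "union"), "mismatch")
})

test_that("SD-from-median normalization meets its invariants", {
  # hand example: (1,2,3) -> (-1,0,1)
  m <- matrix(c(1, 2, 3, 7, 7, 7), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  ann <- data.frame(sample_id = c("a", "b", "c"), patient_id = 1:3,
                    study_id = "s", cancer_type = "ct",
                    sample_class = "metastasis")
  comp <- centerScaleWithinStrata(m, ann)
  expect_equal(unname(sduMatrix(comp)["g1", ]), c(-1, 0, 1))
  expect_equal(unname(sduMatrix(comp)["g2", ]), c(0, 0, 0))
  # shift invariance per stratum
  comp2 <- centerScaleWithinStrata(m + 5, ann)
  expect_equal(sduMatrix(comp2), sduMatrix(comp))
  # idempotence: median-0 / SD-1 is a fixed point
  again <- centerScaleWithinStrata(sduMatrix(comp), ann)
  expect_equal(sduMatrix(again), sduMatrix(comp), tolerance = 1e-12)
  # full synthetic compendium invariant within 1e-9
  env <- defaultCompendium(11)
  v <- validateStrataNormalization(env$comp)
  expect_lt(v$maxAbsMedian, 1e-9)
  expect_lt(v$maxAbsSDminus1, 1e-9)
})

test_that("singleton strata warn and propagate missingness", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  ann <- data.frame(sample_id = c("a", "b", "c"), patient_id = 1:3,
                    study_id = c("s1", "s1", "s2"), cancer_type = "ct",
                    sample_class = "PDX")
  expect_warning(comp <- centerScaleWithinStrata(m, ann), "size 1")
  expect_true(all(is.na(sduMatrix(comp)[, "c"])))
  expect_false(anyNA(sduMatrix(comp)[, c("a", "b")]))
  expect_error(centerScaleWithinStrata(
    matrix(1, 1, 1, dimnames = list("g", "zz")), ann), "unknown stratum")
})

test_that("paired normalization divides deltas by the met+zero-primary SD", {
  genes <- c("g1", "g2")
  met <- matrix(c(2, -2, 0, 0), 2, 2, byrow = TRUE,
                dimnames = list(genes, c("m1", "m2")))
  pri <- matrix(0, 2, 2, dimnames = list(genes, c("p1", "p2")))
  pairs <- data.frame(met_id = c("m1", "m2"), primary_id = c("p1", "p2"),
                      study_id = "s1")
  pn <- pairedNormalize(met, pri, pairs)
  # SD across (2, -2, 0, 0) = 1.633 -> +/- 1.2247
  expect_equal(unname(pn$delta["g1", ]), c(2, -2) / sd(c(2, -2, 0, 0)))
  expect_equal(unname(pn$delta["g1", "m1"]), 1.2247, tolerance = 1e-4)
  expect_equal(unname(pn$delta["g2", ]), c(0, 0))
  # met == primary -> all zeros
  pn0 <- pairedNormalize(pri, pri,
                         data.frame(met_id = c("p1", "p2"),
                                    primary_id = c("p1", "p2"),
                                    study_id = "s1"))
  expect_true(all(pn0$delta == 0))
  # scaling all of a study's deltas by c > 0 leaves outputs unchanged
  met3 <- pri + 3 * (met - pri)
  dimnames(met3) <- dimnames(met)
  expect_equal(pairedNormalize(met3, pri, pairs)$delta, pn$delta)
  # adding a per-gene constant to both members of a pair changes nothing
  expect_equal(pairedNormalize(met + 5, pri + 5, pairs)$delta, pn$delta)
  expect_error(pairedNormalize(met, pri, pairs[1, ]), "unpaired")
})

test_that("lymphoma-like filtering standardizes marker and signature scores", {
  set.seed(8)
  n <- 9
  m <- matrix(rnorm(5 * n, 0, 1), 5, n,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
  m["g1", ] <- c(rep(0, n - 1), 4)  # spike: z = sqrt(n) = 3 exactly
  fl <- filterLymphomaLike(m, "g1", c("g4", "g5"))
  expect_equal(fl$removed, "s9")
  expect_equal(fl$report$markerZ[9], 3, tolerance = 1e-12)
  # all-identical samples: nothing removed
  flat <- matrix(1, 3, 5, dimnames = list(paste0("g", 1:3), paste0("s", 1:5)))
  expect_length(filterLymphomaLike(flat, "g1", "g2")$removed, 0)
  expect_error(filterLymphomaLike(m, "absent", "g2"), "absent")
  # spiked signature alone triggers removal
  m2 <- matrix(rnorm(5 * 50), 5, 50,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:50)))
  m2[c("g4", "g5"), 7] <- 9
  fl2 <- filterLymphomaLike(m2, "g1", c("g4", "g5"))
  expect_equal(fl2$removed, "s7")
  expect_equal(fl2$report$reason[7], "signature")
})
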