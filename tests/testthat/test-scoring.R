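toy_def <- function(tab) {
  defaults <- data.frame(variant_id = sprintf("v%03d", seq_len(nrow(tab))),
                         chromosome = "1",
                         position = seq_len(nrow(tab)) * 1000L,
                         stringsAsFactors = FALSE)
  for (nm in names(tab)) defaults[[nm]] <- tab[[nm]]
  ScoreDefinition("toy", defaults)
}

test_that("harmonization resolves matches, flips and complements, and drops the rest", {
  dm <- make_dosage_matrix(matrix(c(0, 1, 2), 1),
                           counted = "A", other = "G")
  # direct match
  hw <- harmonizeWeights(toy_def(data.frame(effect_allele = "A",
                                            other_allele = "G",
                                            effect_weight = 0.3)), dm)
  expect_equal(as.character(hw@entries$action), "match")
  expect_equal(hw@entries$weight, 0.3)
  expect_equal(hw@offset, 0)

  # flip: contribution must equal 0.3 * (2 - dosage)
  hw <- harmonizeWeights(toy_def(data.frame(effect_allele = "G",
                                            other_allele = "A",
                                            effect_weight = 0.3)), dm)
  expect_equal(as.character(hw@entries$action), "flip")
  sv <- computeRawScore(dm, hw)
  expect_equal(unname(rawScores(sv)), 0.3 * (2 - c(0, 1, 2)),
               tolerance = 1e-12)

  # complement match (T/C vs matrix A/G)
  hw <- harmonizeWeights(toy_def(data.frame(effect_allele = "T",
                                            other_allele = "C",
                                            effect_weight = 0.5)), dm)
  expect_equal(as.character(hw@entries$action), "complement_match")

  # palindromic A/T dropped under default policy
  dmp <- make_dosage_matrix(matrix(c(0, 1, 2), 1),
                            counted = "A", other = "T")
  hw <- harmonizeWeights(toy_def(data.frame(effect_allele = "A",
                                            other_allele = "T",
                                            effect_weight = 0.5)), dmp)
  expect_equal(as.character(hw@dropped$reason), "ambiguous_palindrome")

  # position absent -> not_found; wrong alleles -> allele_mismatch
  hw <- harmonizeWeights(
    ScoreDefinition("x", data.frame(
      variant_id = c("a", "b"), chromosome = "1",
      position = c(1000L, 9999L), effect_allele = c("C", "A"),
      other_allele = c("G", "G"), effect_weight = c(0.1, 0.2))), dm)
  expect_setequal(as.character(hw@dropped$reason),
                  c("allele_mismatch", "not_found"))
  expect_equal(nrow(hw@entries) + nrow(hw@dropped), 2L)
})

test_that("frequency_align orients palindromic variants by allele frequency", {
  # counted-allele frequency 0.1 (clearly minor)
  d <- matrix(c(rep(0, 8), 1, 1), 1)
  dmp <- make_dosage_matrix(d, counted = "A", other = "T")
  same <- toy_def(data.frame(effect_allele = "A", other_allele = "T",
                             effect_weight = 0.4,
                             effect_allele_frequency = 0.1))
  hw <- harmonizeWeights(same, dmp, "frequency_align")
  expect_equal(as.character(hw@entries$action), "match")
  expect_equal(hw@entries$weight, 0.4)

  flipped <- toy_def(data.frame(effect_allele = "A", other_allele = "T",
                                effect_weight = 0.4,
                                effect_allele_frequency = 0.9))
  hw <- harmonizeWeights(flipped, dmp, "frequency_align")
  expect_equal(as.character(hw@entries$action), "complement_flip")
  expect_equal(hw@entries$weight, -0.4)

  ambiguous <- toy_def(data.frame(effect_allele = "A", other_allele = "T",
                                  effect_weight = 0.4,
                                  effect_allele_frequency = 0.5))
  hw <- harmonizeWeights(ambiguous, dmp, "frequency_align")
  expect_equal(as.character(hw@dropped$reason), "ambiguous_palindrome")

  no_freq <- toy_def(data.frame(effect_allele = "A", other_allele = "T",
                                effect_weight = 0.4))
  expect_error(harmonizeWeights(no_freq, dmp, "frequency_align"),
               "effect_allele_frequency")
})

test_that("raw scoring matches hand arithmetic and handles missing-data policies", {
  d <- matrix(c(0, 1, 2), 3, 1)
  dm <- make_dosage_matrix(d)
  def <- toy_def(data.frame(effect_allele = rep("A", 3),
                            other_allele = rep("G", 3),
                            effect_weight = c(0.1, -0.2, 0.3)))
  hw <- harmonizeWeights(def, dm)
  expect_equal(unname(rawScores(computeRawScore(dm, hw))), 0.4)

  zero <- toy_def(data.frame(effect_allele = rep("A", 3),
                             other_allele = rep("G", 3),
                             effect_weight = rep(0, 3)))
  expect_equal(unname(rawScores(computeRawScore(
    dm, harmonizeWeights(zero, dm)))), 0)

  # one missing dosage under mean_dosage: contribution = weight * mean(others)
  d2 <- matrix(c(NA, 1, 1, 1), 1)
  dm2 <- make_dosage_matrix(d2)
  def1 <- toy_def(data.frame(effect_allele = "A", other_allele = "G",
                             effect_weight = 0.7))
  hw2 <- harmonizeWeights(def1, dm2)
  raw <- rawScores(computeRawScore(dm2, hw2, "mean_dosage"))
  expect_equal(unname(raw[1]), 0.7 * 1)
  raw0 <- rawScores(computeRawScore(dm2, hw2, "zero"))
  expect_equal(unname(raw0[1]), 0)
  rawf <- rawScores(computeRawScore(dm2, hw2, "frequency_expected",
                                    frequencies = 0.25))
  expect_equal(unname(rawf[1]), 0.7 * 0.5)
  expect_error(computeRawScore(dm2, hw2, "frequency_expected"),
               "requires per-variant frequencies")
})

test_that("standardization uses sample or reference moments and rejects degenerate input", {
  sv <- .sv <- standardizeScores(metapgs:::.ScoreVector(c("a", "b", "c"),
                                                        c(1, 2, 3)))
  expect_equal(mean(standardizedScores(sv)), 0)
  expect_equal(sd(standardizedScores(sv)), 1)
  one <- standardizeScores(metapgs:::.ScoreVector("a", 5),
                           reference = c(0, 1))
  expect_equal(unname(standardizedScores(one)), 5)
  two <- standardizeScores(metapgs:::.ScoreVector(c("a", "b"), c(10, 20)),
                           reference = c(10, 10))
  expect_equal(unname(standardizedScores(two)), c(0, 1))
  expect_error(standardizeScores(metapgs:::.ScoreVector(c("a", "b"),
                                                        c(1, 1))),
               "zero variance")
})

test_that("scoring equals the brute-force double loop on random instances", {
  set.seed(21)
  for (rep in 1:10) {
    nv <- sample(5:50, 1); ns <- sample(5:100, 1)
    dm <- random_dosage_matrix(nv, ns)
    w <- rnorm(nv)
    def <- ScoreDefinition("r", cbind(variantInfo(dm)[
      c("variant_id", "chromosome", "position")],
      data.frame(effect_allele = variantInfo(dm)$counted_allele,
                 other_allele = variantInfo(dm)$other_allele,
                 effect_weight = w)))
    hw <- harmonizeWeights(def, dm)
    got <- unname(rawScores(computeRawScore(dm, hw)))
    want <- brute_force_score(dosages(dm), hw@entries$matrix_index,
                              hw@entries$weight, hw@offset)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("allele flipping in the definition leaves standardized scores invariant", {
  set.seed(22)
  dm <- random_dosage_matrix(20, 50)
  vi <- variantInfo(dm)
  w <- rnorm(20)
  def <- ScoreDefinition("fwd", data.frame(
    variant_id = vi$variant_id, chromosome = vi$chromosome,
    position = vi$position, effect_allele = vi$counted_allele,
    other_allele = vi$other_allele, effect_weight = w))
  flip <- sample(c(TRUE, FALSE), 20, replace = TRUE)
  def2 <- ScoreDefinition("swapped", data.frame(
    variant_id = vi$variant_id, chromosome = vi$chromosome,
    position = vi$position,
    effect_allele = ifelse(flip, vi$other_allele, vi$counted_allele),
    other_allele = ifelse(flip, vi$counted_allele, vi$other_allele),
    effect_weight = ifelse(flip, -w, w)))
  s1 <- computeRawScore(dm, harmonizeWeights(def, dm))
  s2 <- computeRawScore(dm, harmonizeWeights(def2, dm))
  # raw scores differ by a constant shared across samples
  expect_lt(diff(range(rawScores(s1) - rawScores(s2))), 1e-12)
  expect_equal(unname(standardizedScores(standardizeScores(s1))),
               unname(standardizedScores(standardizeScores(s2))),
               tolerance = 1e-12)
})

test_that("missing-policy consistency and permutation equivariance hold", {
  set.seed(23)
  dm <- random_dosage_matrix(10, 30)
  vi <- variantInfo(dm)
  def <- ScoreDefinition("p", data.frame(
    variant_id = vi$variant_id, chromosome = vi$chromosome,
    position = vi$position, effect_allele = vi$counted_allele,
    other_allele = vi$other_allele, effect_weight = rnorm(10)))
  hw <- harmonizeWeights(def, dm)
  freqs <- rowMeans(dosages(dm)) / 2
  a <- rawScores(computeRawScore(dm, hw, "mean_dosage"))
  b <- rawScores(computeRawScore(dm, hw, "zero"))
  cc <- rawScores(computeRawScore(dm, hw, "frequency_expected",
                                  frequencies = freqs))
  expect_equal(a, b); expect_equal(a, cc)

  perm <- sample(ncol(dm))
  dmp <- dm[, perm]
  sp <- rawScores(computeRawScore(dmp, harmonizeWeights(def, dmp)))
  expect_equal(unname(sp), unname(a[perm]))
})
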