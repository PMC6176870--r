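# shared builders and independent oracles for the test suite

make_dosage_matrix <- function(d, chrom = NULL, pos = NULL,
                               counted = NULL, other = NULL) {
  v <- nrow(d)
  DosageMatrix(d, data.frame(
    variant_id = sprintf("v%03d", seq_len(v)),
    chromosome = if (is.null(chrom)) rep("1", v) else chrom,
    position = if (is.null(pos)) seq_len(v) * 1000L else as.integer(pos),
    counted_allele = if (is.null(counted)) rep("A", v) else counted,
    other_allele = if (is.null(other)) rep("G", v) else other,
    stringsAsFactors = FALSE),
    sprintf("s%03d", seq_len(ncol(d))))
}

random_dosage_matrix <- function(n_var, n_samp, missing_rate = 0) {
  d <- matrix(sample(0:2, n_var * n_samp, replace = TRUE), n_var, n_samp)
  if (missing_rate > 0)
    d[runif(length(d)) < missing_rate] <- NA
  make_dosage_matrix(d)
}

# brute-force additive score: explicit double loop, no linear algebra
brute_force_score <- function(d, idx, w, offset) {
  raw <- numeric(ncol(d))
  for (s in seq_len(ncol(d))) {
    acc <- offset
    for (k in seq_along(idx)) acc <- acc + w[k] * d[idx[k], s]
    raw[s] <- acc
  }
  raw
}

# independent greedy thinning: direct restatement of the rule using a
# precomputed full correlation matrix
oracle_greedy_thin <- function(variants, dmat, r2_max, window) {
  d <- dosages(dmat)
  ids <- variantInfo(dmat)$variant_id
  cm <- suppressWarnings(cor(t(d)))^2
  cm[is.na(cm)] <- 0
  ord <- order(variants$p_value, variants$chromosome, variants$position)
  v <- variants[ord, ]
  kept <- integer(0)
  for (k in seq_len(nrow(v))) {
    ok <- TRUE
    for (j in kept) {
      if (v$chromosome[k] == v$chromosome[j] &&
          abs(v$position[k] - v$position[j]) <= window) {
        r2 <- cm[match(v$variant_id[k], ids), match(v$variant_id[j], ids)]
        if (r2 > r2_max) { ok <- FALSE; break }
      }
    }
    if (ok) kept <- c(kept, k)
  }
  v[kept, ]
}

# brute-force concordance with delayed entry: O(n^2) over ordered pairs
oracle_concordance <- function(score, entry, exit, is_event, strata) {
  conc <- 0; pairs <- 0
  n <- length(score)
  for (i in seq_len(n)) {
    if (!is_event[i]) next
    for (j in seq_len(n)) {
      if (j == i || strata[j] != strata[i]) next
      if (entry[j] < exit[i] && exit[j] > exit[i]) {
        pairs <- pairs + 1
        if (score[i] > score[j]) conc <- conc + 1
        else if (score[i] == score[j]) conc <- conc + 0.5
      }
    }
  }
  list(c = conc / pairs, pairs = pairs)
}

# exact HWE p by direct enumeration with exact binomial coefficients
oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_bb + n_ab
  nr <- min(na, 2 * n - na)
  hets <- seq(nr %% 2, nr, by = 2)
  pr <- vapply(hets, function(h) {
    hom_r <- (nr - h) / 2
    hom_c <- (2 * n - nr - h) / 2
    exp(lfactorial(n) - lfactorial(hom_r) - lfactorial(h) -
          lfactorial(hom_c) + h * log(2) +
          lfactorial(nr) + lfactorial(2 * n - nr) - lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n_ab, hets)] * (1 + 1e-10)])
}

# small survival cohort for evaluation tests
sim_simple_cohort <- function(n, beta, baseline = 0.0011, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  haz <- baseline * exp(beta * z + ifelse(sex == "female", log(0.5), 0))
  t_cad <- rexp(n, haz)
  t_death <- rexp(n, 0.003)
  exit <- pmin(t_cad, t_death, 75)
  status <- ifelse(t_cad <= pmin(t_death, 75), "cad",
                   ifelse(t_death <= 75, "competing_death", "censored"))
  list(outcomes = data.frame(sample_id = sprintf("s%05d", seq_len(n)),
                             entry_age = 0, exit_age = exit,
                             status = status, stringsAsFactors = FALSE),
       score = z, sex = sex)
}
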