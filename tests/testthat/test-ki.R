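# One-step pair enumeration, the counting Ki estimator, and deviation
# scoring against an expected spectrum.

pairs75 <- enumerate_one_step_pairs()

test_that("the standard code yields exactly 75 one-step pairs", {
  expect_length(pairs75$pairs, 75L)
  # Asp-Tyr is reachable (GAC <-> TAC); Phe-Lys is not
  expect_true("D-Y" %in% pairs75$pairs)
  expect_false("F-K" %in% pairs75$pairs)
  # exhaustive check that F and K codons always differ at >= 2 positions
  code <- ccsplus:::GENETIC_CODE_TABLE()
  fc <- names(code)[code == "F"]; kc <- names(code)[code == "K"]
  for (a in fc) for (b in kc) {
    nd <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_gte(nd, 2L)
  }
  # every listed codon edge differs at exactly one position
  nd <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
               pairs75$codon_edges$codon1, pairs75$codon_edges$codon2)
  expect_true(all(nd == 1L))
})

test_that("opportunities conserve the total single-hit neutral expectation", {
  set.seed(3)
  sim <- simulate_codon_pair(n_codons = 2000L, seed = 13)
  est <- estimate_ki(sim$seqs)
  M <- ccsplus:::codon_opportunity_matrix(pairs75)
  # per-codon totals = 9 minus neighbors that are stops
  c1 <- ccsplus:::split_codons(sim$seqs[[1]])
  c2 <- ccsplus:::split_codons(sim$seqs[[2]])
  expected_total <- (sum(rowSums(M)[c1]) + sum(rowSums(M)[c2])) / 2
  expect_equal(sum(est$table$opportunity) + est$syn_opportunity,
               expected_total, tolerance = 1e-9)
})

test_that("identical sequences leave the spectrum undefined", {
  s <- strrep("ATGGCT", 50L)
  expect_warning(est <- estimate_ki(c(a = s, b = s)), "undefined")
  expect_true(est$undefined)
  expect_equal(sum(est$table$count), 0L)
  expect_true(all(is.na(est$table$ki)))
})

test_that("neutral simulation recovers Ki ~ 1 for every pair type", {
  sim <- simulate_codon_pair(ks_target = 0.2, n_codons = 6e4L, seed = 101)
  est <- estimate_ki(sim$seqs)
  expect_false(est$undefined)
  ki <- est$table$ki[est$table$opportunity > 50]
  expect_equal(mean(ki), 1, tolerance = 0.1)
  expect_true(all(abs(ki - 1) < 1))
})

test_that("a zeroed pair type is never observed", {
  rates <- setNames(rep(1, 75), pairs75$pairs)
  rates["A-T"] <- 0
  # low divergence: convergent two-step paths that mimic a one-step
  # change (e.g. V->A and V->I->T ending in GCx/ACx) are vanishingly rare
  sim <- simulate_codon_pair(rates, ks_target = 0.02, n_codons = 2e4L,
                             seed = 7)
  est <- estimate_ki(sim$seqs)
  expect_equal(est$table$count[est$table$pair == "A-T"], 0L)
})

test_that("a structured spectrum is recovered (rank and R^2)", {
  truth <- example_ki_spectrum()
  sim <- simulate_codon_pair(truth, ks_target = 0.15, n_codons = 1e5L,
                             seed = 211)
  est <- estimate_ki(sim$seqs)
  ok <- est$table$opportunity > 0 & !is.na(est$table$ki)
  r2 <- summary(lm(est$table$ki[ok] ~ truth[est$table$pair[ok]]))$r.squared
  expect_gt(r2, 0.9)
  expect_gt(cor(est$table$ki[ok], truth[est$table$pair[ok]],
                method = "spearman"), 0.9)
})

test_that("doubling the alignment roughly halves the sampling variance", {
  truth <- example_ki_spectrum()
  est_at <- function(n, seeds) vapply(seeds, function(s) {
    sim <- simulate_codon_pair(truth, ks_target = 0.15, n_codons = n,
                               seed = s)
    e <- estimate_ki(sim$seqs)$table
    e$ki[e$pair == "A-S"]
  }, numeric(1))
  v1 <- var(est_at(5e3L, 1:14))
  v2 <- var(est_at(1e4L, 101:114))
  expect_lt(v2, v1)                    # variance shrinks with length
  expect_lt(v2 / v1, 1.25)             # and roughly halves
})

test_that("ranking is a permutation with deterministic tie-breaks", {
  sim <- simulate_codon_pair(n_codons = 5e3L, seed = 19)
  est <- estimate_ki(sim$seqs)
  expect_setequal(est$table$rank, 1:75)
  # ties (e.g. zero-count pairs) are ordered by pair name
  zeros <- est$table[est$table$count == 0L & est$table$opportunity > 0, ]
  if (nrow(zeros) > 1L)
    expect_equal(zeros$pair[order(zeros$rank)], sort(zeros$pair))
})

test_that("deviation z-scores, the convergent set and summaries", {
  idx <- data.frame(pair = c("R-W", "D-Y", "A-T"),
                    mean = c(2, 1, 1.5), sd = c(0.5, 0.5, 0.25))
  class(idx) <- c("universal_index", "data.frame")
  obs <- list(p1 = c("R-W" = 3, "D-Y" = 1.2, "A-T" = 1.5))
  rep1 <- compute_deviations(obs, idx, threshold = 2.5)
  expect_equal(rep1$z$p1, c(2, 0.4, 0), ignore_attr = TRUE)
  expect_length(rep1$convergent_pairs, 0L)

  z <- data.frame(pair = c("R-W", "S-N"),
                  t1 = c(6.292, -1.0), t2 = c(4.749, -3.0),
                  t3 = c(3.617, -2.0))
  rep2 <- deviation_report(z, threshold = 2.5)
  expect_equal(rep2$convergent_pairs, "R-W")         # S-N fails in t1/t3
  s <- summarize_deviation_table(rep2)
  expect_equal(unname(s$row_averages["R-W"]), 4.886)
  z$t1[2] <- -2.6; z$t3[2] <- -2.7
  expect_equal(deviation_report(z, 2.5)$convergent_pairs,
               c("R-W", "S-N"))
  # all-zero report
  z0 <- data.frame(pair = "R-W", t1 = 0, t2 = 0)
  s0 <- summarize_deviation_table(deviation_report(z0))
  expect_equal(unname(s0$row_averages), 0)
  expect_equal(s0$mean_abs_row_average, 0)
})

test_that("the convergent set matches an independent filter on random data", {
  set.seed(55)
  for (rep in 1:40) {
    z <- data.frame(pair = pairs75$pairs,
                    a = rnorm(75, 0, 2), b = rnorm(75, 0, 2),
                    c = rnorm(75, 0, 2))
    got <- deviation_report(z, threshold = 2)$convergent_pairs
    want <- z$pair[abs(z$a) > 2 & abs(z$b) > 2 & abs(z$c) > 2]
    expect_identical(got, want)
  }
})

test_that("the expected spectrum aggregates reference pairs with n >= 3", {
  truth <- example_ki_spectrum()
  specs <- lapply(1:4, function(s)
    estimate_ki(simulate_codon_pair(truth, ks_target = 0.15,
                                    n_codons = 1.5e4L, seed = s)$seqs))
  expect_error(universal_index(specs[1:2]), "at least 3")
  idx <- universal_index(specs)
  expect_equal(nrow(idx), 75L)
  expect_true(all(idx$sd > 0 | is.na(idx$sd)))
  f <- withr::local_tempfile(fileext = ".tsv")
  idx$sd[is.na(idx$sd) | idx$sd == 0] <- 0.1
  write_universal_index(idx, f)
  expect_equal(read_universal_index(f)$mean, idx$mean, tolerance = 1e-12)
})
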