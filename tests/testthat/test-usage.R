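# Amino-acid usage convergence: compositions, the three outlier
# criteria, the resampling null, location stratification, GC by site
# class, biosynthetic cost and Fisher enrichment.

test_that("compositions count, normalize and skip non-standard residues", {
  p <- compute_composition("AAAA", species = "t")
  expect_equal(unname(p$freqs["A"]), 1)
  p2 <- compute_composition(c("ACDE", "ACDE"))
  expect_equal(unname(p2$freqs[c("A", "C", "D", "E")]), rep(0.25, 4))
  p3 <- compute_composition("ACXDEXX")
  expect_equal(p3$skipped, 3L)
  expect_equal(sum(p3$counts), 4L)
  expect_equal(sum(p3$freqs), 1)
})

test_that("the 2x2 usage chi-square matches hand computation and chisq.test", {
  r <- chi_square_usage(c(300, 700), c(200, 800))
  expect_equal(r$statistic, 2000 * (300 * 800 - 700 * 200)^2 /
                 (1000 * 1000 * 500 * 1500))
  expect_equal(r$statistic, 26.6667, tolerance = 1e-4)
  expect_equal(r$p_value, 2.4e-7, tolerance = 0.05)
  expect_equal(chi_square_usage(c(120, 880), c(120, 880))$p_value, 1)
  expect_equal(chi_square_usage(c(0, 100), c(0, 100))$statistic, 0)
  expect_equal(chi_square_usage(c(0, 100), c(0, 100))$p_value, 1)
  set.seed(5)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 200) + 1, 2)
    ours <- chi_square_usage(tab[1, ], tab[2, ])
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

make_profile <- function(id, freqs, total = 1e5) {
  counts <- round(freqs / sum(freqs) * total)
  structure(list(species = id, counts = setNames(as.integer(counts),
                                                 names(freqs)),
                 freqs = counts / sum(counts), skipped = 0L),
            class = "aa_usage_profile")
}

test_that("outlier flags obey the three criteria on forced examples", {
  base <- setNames(rep(0.05, 20), ccsplus:::AA_LETTERS)
  # reference panel: Ala frequencies 1..7 (%), focal 8,9,10 (%)
  mk <- function(id, ala) {
    f <- base; f["A"] <- ala / 100
    make_profile(id, f / sum(f))
  }
  reference <- lapply(1:7, function(i) mk(paste0("r", i), i))
  focal <- lapply(8:10, function(i) mk(paste0("f", i - 7), i))
  pairs <- setNames(c("r1", "r2", "r3"), c("f1", "f2", "f3"))
  expect_error(flag_outlier_aas(focal, reference[1:5], pairs),
               "at least 8")
  reference <- c(reference, list(mk("r8", 3.5)))
  flags <- flag_outlier_aas(focal, reference, pairs)
  ala <- flags[flags$aa == "A", ]
  expect_equal(ala$direction, "over")
  expect_true(ala$flagged)
  # push one focal below Q3: criterion (i) fails
  focal2 <- list(mk("f1", 8), mk("f2", 9), mk("f3", 3))
  flags2 <- flag_outlier_aas(focal2, reference, pairs)
  expect_equal(flags2[flags2$aa == "A", "direction"], "none")
  expect_false(any(flags2$flagged))
})

test_that("random panels match an independent re-implementation of the rules", {
  set.seed(77)
  for (rep in 1:60) {
    n_ref <- 12L
    ids <- c(paste0("r", 1:n_ref), paste0("f", 1:3))
    profs <- lapply(ids, function(id) {
      f <- rgamma(20, shape = 8); f <- f / sum(f)
      make_profile(id, setNames(f, ccsplus:::AA_LETTERS),
                   total = sample(5e4:2e5, 1))
    })
    names(profs) <- ids
    pairs <- setNames(c("r1", "r2", "r3"), c("f1", "f2", "f3"))
    flags <- flag_outlier_aas(profs[n_ref + 1:3], profs[1:n_ref], pairs)
    pool_ids <- ids
    for (aa in ccsplus:::AA_LETTERS) {
      vals <- setNames(vapply(profs, function(p) p$freqs[[aa]], numeric(1)),
                       pool_ids)
      want <- oracle_flag_aa(
        vals, paste0("f", 1:3), as.list(pairs),
        counts_aa = setNames(vapply(profs, function(p) p$counts[[aa]],
                                    numeric(1)), pool_ids),
        counts_total = setNames(vapply(profs, function(p) sum(p$counts),
                                       numeric(1)), pool_ids))
      got <- flags[flags$aa == aa, ]
      expect_equal(if (got$flagged) got$direction else "none", want,
                   info = paste("rep", rep, "aa", aa))
    }
  }
})

test_that("resampling null is deterministic and handles degenerate panels", {
  set.seed(1)
  reference <- lapply(1:10, function(i) {
    f <- rgamma(20, 50); make_profile(paste0("r", i),
                                      setNames(f / sum(f),
                                               ccsplus:::AA_LETTERS))
  })
  r1 <- resample_significance(reference, replicates = 400, seed = 9)
  r2 <- resample_significance(reference, replicates = 400, seed = 9)
  expect_identical(r1$n_over, r2$n_over)
  expect_identical(r1$p_total_outliers, r2$p_total_outliers)
  # two identical reference profiles: pseudo-genomes equal them; with all
  # pooled values tied no amino acid can sit strictly outside a quartile
  same <- replicate(2, reference[[1]], simplify = FALSE)
  same[[2]]$species <- "r2dup"
  r3 <- resample_significance(same, replicates = 50, seed = 2)
  expect_equal(r3$p_total_outliers, 0)
  expect_equal(r3$p_under, 0)
  expect_true(is.na(r3$p_over_given_under))
})

test_that("single-AA quartile exceedance rate matches independence estimate", {
  # large iid continuous panel, criterion (i) alone for one amino acid:
  # P(all 3 pseudo-focal beyond Q3) ~ 0.25^3 per direction
  set.seed(42)
  n_ref <- 200L
  reference <- lapply(seq_len(n_ref), function(i) {
    f <- rgamma(20, 40); make_profile(paste0("r", i),
                                      setNames(f / sum(f),
                                               ccsplus:::AA_LETTERS))
  })
  ref <- do.call(rbind, lapply(reference, function(p) p$freqs))
  reps <- 3000L
  hits <- 0L
  for (r in seq_len(reps)) {
    pseudo <- vapply(1:20, function(a) sample(ref[, a], 3L, TRUE), numeric(3))
    pseudo <- pseudo / rowSums(pseudo)
    pool <- c(ref[, 1], pseudo[, 1])
    q3 <- quantile(pool, 0.75, names = FALSE)
    if (all(pseudo[, 1] > q3)) hits <- hits + 1L
  }
  p_hat <- hits / reps
  p_theory <- 0.25^3
  # renormalization couples the 20 draws only weakly
  expect_lt(abs(p_hat - p_theory),
            4 * sqrt(p_theory * (1 - p_theory) / reps) + 0.005)
})

test_that("location stratification partitions counts exactly", {
  proteome <- c(g1 = "AAAA", g2 = "CCCC", g3 = "DDDD", g4 = "AACC")
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    location = c("membrane", "intracellular", "membrane"))
  comparator <- c(h1 = "ACDE")
  out <- stratify_usage_by_location(proteome, ann, comparator)
  expect_setequal(unique(out$location),
                  c("membrane", "intracellular", "unlabelled"))
  mem <- out[out$location == "membrane", ]
  expect_equal(mem$freq[mem$aa == "A"], 0.5)
  expect_equal(mem$freq[mem$aa == "D"], 0.5)
  # counts conserved: location compositions recombine to the whole
  whole <- compute_composition(proteome)
  expect_equal(
    (4 * out$freq[out$location == "membrane"] * 2 +
       4 * out$freq[out$location == "intracellular"] +
       4 * out$freq[out$location == "unlabelled"]) / 16,
    unname(whole$freqs), tolerance = 1e-12)
})

test_that("GC by site class separates coding, 4-fold and intron sites", {
  out <- gc_by_site_class("GGCGGT")
  expect_equal(out$gc[out$class == "coding"], 5 / 6)
  expect_equal(out$n_sites[out$class == "fourfold_third"], 2)
  expect_equal(out$gc[out$class == "fourfold_third"], 1 / 2)

  at <- gc_by_site_class("AATATT", introns = "ATATAT")
  expect_true(all(at$gc[at$n_sites > 0] == 0))

  expect_error(gc_by_site_class("TAAGGC"), "internal stop")
  expect_silent(gc_by_site_class("GGCTAA"))   # terminal stop allowed
  expect_error(gc_by_site_class("GGCGG"), "divisible by 3")
})

test_that("mean HEB cost is the frequency-weighted average", {
  costs <- setNames(rep(1, 20), ccsplus:::AA_LETTERS)
  costs["G"] <- 10; costs["A"] <- 12
  prof <- compute_composition("GA")
  expect_equal(mean_heb(prof, costs), 11)
  prof2 <- compute_composition("GGGG")
  expect_equal(mean_heb(prof2, costs), 10)
  expect_equal(mean_heb(prof, costs[sample(20)]), 11)  # order-invariant
  packaged <- read_heb_table()
  expect_length(packaged, 20L)
  expect_true(all(packaged > 0))
  expect_gt(mean_heb(prof2, packaged), 0)
})

test_that("Fisher enrichment reproduces exact hypergeometric tails", {
  # inclusive background counts 104/5155 against the 4/73 gene set
  r <- fisher_enrichment(4, 73, 104, 5155, alternative = "greater",
                        background_includes_set = TRUE)
  expect_equal(r$table, matrix(c(4, 69, 100, 4982), 2, byrow = TRUE))
  expect_equal(r$p_value, oracle_hyper_tail(4, 73, 100, 5155 - 73),
               tolerance = 1e-12)
  expect_equal(r$p_value, 0.059, tolerance = 0.02)

  # membrane localization: 35/73 vs background 26%
  r2 <- fisher_enrichment(35, 73, round(0.26 * 5155), 5155,
                          alternative = "greater")
  expect_lt(r2$p_value, 1e-3)

  # hits at the expected proportion: no enrichment
  r3 <- fisher_enrichment(10, 100, 100, 1000,
                          background_includes_set = FALSE)
  expect_equal(r3$odds_ratio, 1, tolerance = 1e-2)
  expect_gte(r3$p_value, 0.5)

  # saturated set with hit-free background: minimal tail
  r4 <- fisher_enrichment(5, 5, 0, 50, background_includes_set = FALSE)
  expect_equal(r4$p_value, 1 / choose(55, 5), tolerance = 1e-12)
})
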