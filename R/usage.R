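# Genome-level convergence in amino-acid usage: composition profiles,
# the three outlier criteria (quartile, decile, paired chi-square), a
# resampling null for outlier counts, location-stratified usage, GC by
# site class, biosynthetic-cost (HEB) scores and Fisher enrichment.

#' Amino-acid usage profile of a proteome
#'
#' @param x path to a protein FASTA, or a character vector of amino-acid
#'   sequences.
#' @param species species id recorded on the profile (defaults to the
#'   file name).
#' @return object of class `aa_usage_profile`: list with `species`,
#'   `counts` (named 20-vector), `freqs` (sum 1) and `skipped`
#'   (non-standard residues dropped).
#' @export
compute_composition <- function(x, species = NULL) {
  if (length(x) == 1L && file.exists(x)) {
    if (is.null(species)) species <- sub("\\.[^.]*$", "", basename(x))
    x <- as.character(Biostrings::readBStringSet(x))
  }
  if (is.null(species)) species <- "proteome"
  chars <- unlist(strsplit(toupper(paste(x, collapse = "")), "", fixed = TRUE))
  counts <- table(factor(chars, levels = AA_LETTERS))
  skipped <- length(chars) - sum(counts)
  counts <- stats::setNames(as.integer(counts), AA_LETTERS)
  total <- sum(counts)
  if (total == 0) stop("no standard amino-acid residues in proteome")
  structure(list(species = species, counts = counts,
                 freqs = counts / total, skipped = skipped),
            class = "aa_usage_profile")
}

#' @export
print.aa_usage_profile <- function(x, ...) {
  cat(sprintf("<aa_usage_profile> %s: %d residues (%d skipped)\n",
              x$species, sum(x$counts), x$skipped))
  invisible(x)
}

#' Outlier criteria settings
#'
#' @param extreme_fraction criterion (ii) extreme fraction of the pooled
#'   ranking set (default 0.10: "top or bottom 10%"); a species is in the
#'   extreme when its rank from the relevant end is at most
#'   `ceiling(extreme_fraction * n)`.
#' @param alpha criterion (iii) chi-square significance level
#'   (default 0.01).
#' @param quantile_type quartile convention passed to [stats::quantile()]
#'   (default 7, R's default; the choice matters only for small panels).
#' @param yates apply Yates continuity correction in criterion (iii)
#'   (default `FALSE`; proteome counts are large).
#' @return list of class `outlier_criteria`.
#' @export
outlier_criteria <- function(extreme_fraction = 0.10, alpha = 0.01,
                             quantile_type = 7L, yates = FALSE) {
  stopifnot(extreme_fraction > 0, extreme_fraction < 0.5,
            alpha > 0, alpha < 1)
  structure(list(extreme_fraction = extreme_fraction, alpha = alpha,
                 quantile_type = quantile_type, yates = yates),
            class = "outlier_criteria")
}

#' Pearson chi-square test of amino-acid usage between two proteomes
#'
#' 2x2 test (1 df) of one amino acid's count against the rest, between a
#' focal proteome and its comparator.  Computed by the exact closed form
#' `N (ad - bc)^2 / (r1 r2 c1 c2)`, without continuity correction by
#' default; a zero margin gives statistic 0 and p = 1.
#'
#' @param focal_counts length-2 numeric: (amino-acid count, all other
#'   residues) in the focal proteome.
#' @param relative_counts same for the comparator.
#' @param yates apply the continuity correction.
#' @return list with `statistic` and `p_value`.
#' @export
chi_square_usage <- function(focal_counts, relative_counts, yates = FALSE) {
  stopifnot(length(focal_counts) == 2L, length(relative_counts) == 2L,
            all(focal_counts >= 0), all(relative_counts >= 0))
  focal_counts <- as.numeric(focal_counts)     # avoid integer overflow
  relative_counts <- as.numeric(relative_counts)
  a <- focal_counts[1L]; b <- focal_counts[2L]
  c <- relative_counts[1L]; d <- relative_counts[2L]
  n <- a + b + c + d
  if (n == 0) stop("empty table")
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(list(statistic = 0, p_value = 1))
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  stat <- n * num^2 / denom
  list(statistic = unname(stat),
       p_value = stats::pchisq(unname(stat), df = 1L, lower.tail = FALSE))
}

# pooled ranking values per AA: reference then focal (rows = species)
pool_freq_matrix <- function(profiles) {
  m <- do.call(rbind, lapply(profiles, function(p) p$freqs))
  rownames(m) <- vapply(profiles, function(p) p$species, character(1))
  m
}

# criteria (i) and (ii) for one AA given pooled values and which rows are
# focal; returns direction "over"/"under"/"none" and the two flags
crit_i_ii <- function(values, is_focal, criteria) {
  foc <- values[is_focal]
  q <- stats::quantile(values, c(0.25, 0.75),
                       type = criteria$quantile_type, names = FALSE)
  n <- length(values)
  k <- ceiling(criteria$extreme_fraction * n)
  dir <- if (all(foc > q[2L])) "over" else if (all(foc < q[1L])) "under" else "none"
  pass_i <- dir != "none"
  # rank from the relevant end; ties share the extreme (min rank)
  pass_ii <- FALSE
  if (dir == "over") {
    r <- rank(-values, ties.method = "min")
    pass_ii <- any(r[is_focal] <= k)
  } else if (dir == "under") {
    r <- rank(values, ties.method = "min")
    pass_ii <- any(r[is_focal] <= k)
  }
  list(direction = dir, pass_i = pass_i, pass_ii = pass_ii)
}

#' Flag convergently over/under-used amino acids
#'
#' An amino acid is flagged when all three criteria hold in the same
#' direction: (i) every focal species lies above the third quartile (or
#' below the first) of the pooled panel (reference plus focal species);
#' (ii) at least one focal species is in the top (or bottom)
#' `extreme_fraction` of the pooled ranks; (iii) each focal species' usage
#' is more extreme than that of its closest non-focal relative, with a
#' 2x2 chi-square p below `alpha`.
#'
#' @param focal list of [compute_composition()] profiles (the focal
#'   genomes).
#' @param reference list of profiles (the reference panel; at least 8).
#' @param pairs named character vector mapping each focal species id to
#'   the species id of its closest relative; relatives are looked up among
#'   `reference` (or `focal`).
#' @param criteria an [outlier_criteria()].
#' @return data frame, one row per amino acid: `aa`, `direction`
#'   (`over`/`under`/`none` from criteria i–ii), `pass_i`, `pass_ii`,
#'   `pass_iii`, `flagged` (all three), and the max criterion-(iii)
#'   p-value across focal species.
#' @export
flag_outlier_aas <- function(focal, reference, pairs,
                             criteria = outlier_criteria()) {
  if (length(reference) < 8L)
    stop("need at least 8 reference profiles for stable quartiles")
  all_prof <- c(reference, focal)
  names(all_prof) <- vapply(all_prof, function(p) p$species, character(1))
  foc_ids <- vapply(focal, function(p) p$species, character(1))
  if (!all(foc_ids %in% names(pairs)))
    stop("every focal species needs a closest relative in `pairs`")
  rel_ids <- pairs[foc_ids]
  if (!all(rel_ids %in% names(all_prof)))
    stop("relative(s) not found among profiles: ",
         paste(setdiff(rel_ids, names(all_prof)), collapse = ", "))
  m <- pool_freq_matrix(all_prof)
  is_focal <- rownames(m) %in% foc_ids
  out <- lapply(AA_LETTERS, function(aa) {
    c12 <- crit_i_ii(m[, aa], is_focal, criteria)
    pass_iii <- FALSE
    max_p <- NA_real_
    if (c12$direction != "none") {
      ps <- vapply(foc_ids, function(f) {
        fp <- all_prof[[f]]; rp <- all_prof[[pairs[[f]]]]
        more_extreme <- if (c12$direction == "over")
          fp$freqs[aa] > rp$freqs[aa] else fp$freqs[aa] < rp$freqs[aa]
        if (!more_extreme) return(1)
        chi_square_usage(
          c(fp$counts[aa], sum(fp$counts) - fp$counts[aa]),
          c(rp$counts[aa], sum(rp$counts) - rp$counts[aa]),
          yates = criteria$yates)$p_value
      }, numeric(1))
      max_p <- max(ps)
      pass_iii <- max_p < criteria$alpha
    }
    data.frame(aa = aa, direction = c12$direction,
               pass_i = c12$pass_i, pass_ii = c12$pass_ii,
               pass_iii = pass_iii,
               flagged = c12$pass_i && c12$pass_ii && pass_iii,
               max_p_iii = max_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Resampling null for the number of outlier amino acids
#'
#' Builds, per replicate, `n_focal` pseudo-genomes by drawing each amino
#' acid's frequency independently from the reference panel's column and
#' renormalizing to 1; pools them with the reference (replacing the focal
#' genomes in the ranking panel by default); applies criteria (i) and
#' (ii); and tallies how many amino acids come out over- or under-used.
#'
#' @param reference list of [compute_composition()] profiles.
#' @param n_focal number of pseudo-genomes per replicate (default 3).
#' @param criteria an [outlier_criteria()].
#' @param replicates Monte-Carlo replicates (reference protocol 1e5;
#'   scale down for quick runs).
#' @param seed integer seed.
#' @param k_total observed total outlier count to score (default 9).
#' @param k_under observed underused count (default 5).
#' @param k_over observed overused count (default 4).
#' @return object of class `resample_result`: list with
#'   `p_total_outliers` = P(total >= k_total), `p_under` =
#'   P(under >= k_under), `p_over_given_under` =
#'   P(over >= k_over | under >= k_under) (NA when the condition never
#'   occurs), the per-replicate tallies and settings.
#' @export
resample_significance <- function(reference, n_focal = 3L,
                                  criteria = outlier_criteria(),
                                  replicates = 1e5, seed = NULL,
                                  k_total = 9L, k_under = 5L, k_over = 4L) {
  stopifnot(length(reference) >= 2L, replicates >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  replicates <- as.integer(replicates)
  ref <- pool_freq_matrix(reference)
  n_ref <- nrow(ref)
  n_over <- integer(replicates)
  n_under <- integer(replicates)
  for (r in seq_len(replicates)) {
    idx <- matrix(sample.int(n_ref, n_focal * 20L, replace = TRUE),
                  n_focal, 20L)
    pseudo <- matrix(ref[cbind(as.vector(idx), rep(1:20, each = n_focal))],
                     n_focal, 20L)
    pseudo <- pseudo / rowSums(pseudo)
    pool <- rbind(ref, pseudo)
    is_focal <- c(rep(FALSE, n_ref), rep(TRUE, n_focal))
    over <- 0L; under <- 0L
    for (a in 1:20) {
      c12 <- crit_i_ii(pool[, a], is_focal, criteria)
      if (c12$pass_i && c12$pass_ii) {
        if (c12$direction == "over") over <- over + 1L else under <- under + 1L
      }
    }
    n_over[r] <- over
    n_under[r] <- under
  }
  total <- n_over + n_under
  cond <- n_under >= k_under
  structure(list(
    p_total_outliers = mean(total >= k_total),
    p_under = mean(cond),
    p_over_given_under = if (any(cond)) mean(n_over[cond] >= k_over) else NA_real_,
    n_over = n_over, n_under = n_under,
    replicates = replicates, seed = seed,
    k_total = k_total, k_under = k_under, k_over = k_over),
    class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf("resampling null (%d replicates):\n", x$replicates))
  cat(sprintf("  P(total outliers >= %d)   = %.4g\n", x$k_total,
              x$p_total_outliers))
  cat(sprintf("  P(underused >= %d)        = %.4g\n", x$k_under, x$p_under))
  cat(sprintf("  P(overused >= %d | under) = %.4g\n", x$k_over,
              x$p_over_given_under))
  invisible(x)
}

#' Amino-acid usage stratified by subcellular location
#'
#' Partitions a proteome by a per-gene location label, computes the
#' composition per class, and reports the delta against a comparator
#' proteome (partitioned the same way when its annotation is given,
#' otherwise against its whole-proteome composition).
#'
#' @param proteome named character vector of protein sequences (names are
#'   gene ids).
#' @param annotation data frame `gene_id`, label (see
#'   [read_annotation()]); genes without a label are grouped under
#'   `"unlabelled"`.
#' @param comparator named character vector for the comparator proteome.
#' @param comparator_annotation optional annotation for the comparator.
#' @return data frame: `location`, `aa`, `freq`, `comparator_freq`,
#'   `delta`.
#' @export
stratify_usage_by_location <- function(proteome, annotation, comparator,
                                       comparator_annotation = NULL) {
  stopifnot(!is.null(names(proteome)))
  lab <- stats::setNames(annotation[[2L]], annotation$gene_id)
  loc <- lab[names(proteome)]
  loc[is.na(loc)] <- "unlabelled"
  comp_all <- compute_composition(comparator, species = "comparator")
  comp_by <- NULL
  if (!is.null(comparator_annotation)) {
    clab <- stats::setNames(comparator_annotation[[2L]],
                            comparator_annotation$gene_id)
    cl <- clab[names(comparator)]
    cl[is.na(cl)] <- "unlabelled"
    comp_by <- split(comparator, cl)
  }
  out <- lapply(split(proteome, loc), function(seqs) {
    prof <- compute_composition(seqs, species = "focal")
    prof
  })
  res <- lapply(names(out), function(l) {
    cf <- if (!is.null(comp_by) && l %in% names(comp_by))
      compute_composition(comp_by[[l]], species = l)$freqs
    else comp_all$freqs
    data.frame(location = l, aa = AA_LETTERS,
               freq = unname(out[[l]]$freqs),
               comparator_freq = unname(cf),
               delta = unname(out[[l]]$freqs - cf),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res
}

# third-position 4-fold degenerate codon prefixes under a given code
fourfold_prefixes <- function(code = GENETIC_CODE_TABLE()) {
  prefixes <- unique(substr(names(code), 1L, 2L))
  keep <- vapply(prefixes, function(p) {
    aas <- code[paste0(p, c("A", "C", "G", "T"))]
    !any(aas == "*") && length(unique(aas)) == 1L
  }, logical(1))
  prefixes[keep]
}

#' GC content by site class
#'
#' @param cds character vector of coding sequences (lengths divisible by
#'   3; internal stop codons are rejected, a terminal stop is allowed).
#' @param introns optional character vector of intron sequences.
#' @return data frame `class` (`coding`, `fourfold_third`, `intron`),
#'   `gc` (fraction), `n_sites`.
#' @details 4-fold degenerate sites are third positions of codons whose
#'   first two bases fully determine the amino acid under the standard
#'   genetic code; they proxy neutrally evolving coding sequence.
#' @export
gc_by_site_class <- function(cds, introns = NULL) {
  cds <- toupper(cds)
  if (any(nchar(cds) %% 3L != 0L))
    stop("CDS length must be divisible by 3")
  code <- GENETIC_CODE_TABLE()
  codons <- unlist(lapply(cds, function(s)
    substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))))
  per_seq_last <- cumsum(vapply(cds, function(s) nchar(s) / 3, numeric(1)))
  aa <- code[codons]
  internal_stop <- which(!is.na(aa) & aa == "*" & !(seq_along(aa) %in% per_seq_last))
  if (length(internal_stop))
    stop("internal stop codon at codon ", internal_stop[1L])
  is_gc <- function(x) {
    x <- x[x %in% c("A", "C", "G", "T")]
    if (!length(x)) return(c(gc = NA_real_, n = 0))
    c(gc = mean(x %in% c("G", "C")), n = length(x))
  }
  all_nt <- unlist(strsplit(codons, "", fixed = TRUE))
  coding <- is_gc(all_nt)
  ff <- substr(codons, 1L, 2L) %in% fourfold_prefixes(code)
  third <- substr(codons[ff], 3L, 3L)
  four <- is_gc(third)
  out <- data.frame(class = c("coding", "fourfold_third"),
                    gc = c(coding[["gc"]], four[["gc"]]),
                    n_sites = c(coding[["n"]], four[["n"]]),
                    stringsAsFactors = FALSE)
  if (!is.null(introns)) {
    intr <- is_gc(unlist(strsplit(toupper(introns), "", fixed = TRUE)))
    out <- rbind(out, data.frame(class = "intron", gc = intr[["gc"]],
                                 n_sites = intr[["n"]]))
  }
  out
}

#' Read the high-energy-bond cost table
#'
#' Biosynthetic cost per amino acid counted as high-energy phosphate
#' bonds (~PO4).  The packaged table (`inst/extdata/heb_costs.tsv`)
#' carries literature values and is plain text, meant to be replaced or
#' edited freely.
#'
#' @param path TSV with columns `aa`, `cost`; defaults to the packaged
#'   table.
#' @return named numeric vector of 20 positive costs.
#' @export
read_heb_table <- function(path = system.file("extdata", "heb_costs.tsv",
                                              package = "ccsplus")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  costs <- stats::setNames(df$cost, df$aa)
  if (!setequal(names(costs), AA_LETTERS) || any(costs <= 0))
    stop("HEB table must give one positive cost per amino acid")
  costs[AA_LETTERS]
}

#' Mean biosynthetic cost of a proteome
#'
#' Frequency-weighted mean high-energy-bond cost,
#' `sum(freq[aa] * cost[aa])`.
#'
#' @param profile an [compute_composition()] profile.
#' @param table named cost vector (see [read_heb_table()]).
#' @return single numeric.
#' @export
mean_heb <- function(profile, table = read_heb_table()) {
  if (!setequal(names(table), AA_LETTERS)) stop("cost table must cover 20 AAs")
  sum(profile$freqs[AA_LETTERS] * table[AA_LETTERS])
}

#' Fisher's exact enrichment test
#'
#' Exact hypergeometric test of category enrichment in a gene set against
#' a background.
#'
#' @param in_set_hits category members in the gene set.
#' @param in_set_total gene-set size.
#' @param background_hits category members in the background.
#' @param background_total background size.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @param background_includes_set if `TRUE` (the common reporting
#'   convention) the background counts contain the gene set and are
#'   reduced to the disjoint complement before testing; if `FALSE` the
#'   background is already disjoint.
#' @return list with `odds_ratio`, `p_value` and the 2x2 `table` tested.
#' @export
fisher_enrichment <- function(in_set_hits, in_set_total, background_hits,
                              background_total,
                              alternative = c("greater", "less", "two.sided"),
                              background_includes_set = TRUE) {
  alternative <- match.arg(alternative)
  stopifnot(in_set_hits <= in_set_total, background_hits <= background_total)
  if (background_includes_set) {
    background_hits <- background_hits - in_set_hits
    background_total <- background_total - in_set_total
    if (background_hits < 0 || background_total < 0)
      stop("background must contain the gene set under the inclusive convention")
  }
  tab <- matrix(c(in_set_hits, in_set_total - in_set_hits,
                  background_hits, background_total - background_hits),
                2L, 2L, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = alternative)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}
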