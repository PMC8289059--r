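# One-step amino-acid exchange rates (Ki): enumeration of the 75
# single-nucleotide-reachable amino-acid pairs, a counting estimator of
# their rates from pairwise codon alignments (scaled to the synonymous
# rate so a neutral pair type has Ki = 1), and deviation scoring against
# an expected cross-taxon ("universal index") spectrum.

pair_label <- function(a1, a2) {
  paste(pmin(a1, a2), pmax(a1, a2), sep = "-")
}

#' Enumerate one-step amino-acid pairs
#'
#' Walks every sense codon's 9 single-base neighbors, drops mutations to
#' stop codons and synonymous changes, and collapses the remaining codon
#' edges to unordered amino-acid pairs.  Under the standard code there
#' are exactly 75 such pairs (the other 115 of the 190 unordered pairs
#' require 2- or 3-base changes).
#'
#' @param code named character vector mapping codons (DNA alphabet) to
#'   one-letter amino acids, stops as `"*"`; defaults to the standard
#'   genetic code.
#' @return object of class `one_step_pairs`: list with `pairs` (sorted
#'   character vector like `"D-Y"`), `codon_edges` (data frame `codon1`,
#'   `codon2`, `pair`, each edge listed once), and `code`.
#' @export
enumerate_one_step_pairs <- function(code = GENETIC_CODE_TABLE()) {
  sense <- names(code)[code != "*"]
  bases <- c("A", "C", "G", "T")
  edges <- list()
  for (cd in sense) for (p in 1:3) for (b in bases) {
    if (substr(cd, p, p) == b) next
    nb <- cd
    substr(nb, p, p) <- b
    if (code[[nb]] == "*" || nb <= cd) next      # each unordered edge once
    a1 <- code[[cd]]; a2 <- code[[nb]]
    if (a1 == a2) next
    edges[[length(edges) + 1L]] <- data.frame(
      codon1 = cd, codon2 = nb, pair = pair_label(a1, a2),
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  structure(list(pairs = sort(unique(edges$pair)),
                 codon_edges = edges, code = code),
            class = "one_step_pairs")
}

#' @export
print.one_step_pairs <- function(x, ...) {
  cat(sprintf("<one_step_pairs> %d unordered amino-acid pairs, %d codon edges\n",
              length(x$pairs), nrow(x$codon_edges)))
  invisible(x)
}

# Per-codon mutational-opportunity matrix: rows = sense codons, columns =
# one-step pairs plus "syn"; entry = number of single-base neighbors of
# that codon realizing the column's change (stop neighbors dropped).
codon_opportunity_matrix <- function(pairs_obj) {
  code <- pairs_obj$code
  sense <- names(code)[code != "*"]
  bases <- c("A", "C", "G", "T")
  cols <- c(pairs_obj$pairs, "syn")
  M <- matrix(0, length(sense), length(cols),
              dimnames = list(sense, cols))
  for (cd in sense) for (p in 1:3) for (b in bases) {
    if (substr(cd, p, p) == b) next
    nb <- cd
    substr(nb, p, p) <- b
    if (code[[nb]] == "*") next
    a1 <- code[[cd]]; a2 <- code[[nb]]
    col <- if (a1 == a2) "syn" else pair_label(a1, a2)
    M[cd, col] <- M[cd, col] + 1
  }
  M
}

split_codons <- function(s) {
  substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
}

#' Estimate the one-step exchange-rate spectrum from a codon pair
#'
#' A counting estimator for closely related species: codon columns
#' differing at exactly one position contribute one observed change
#' (synonymous, or one of the 75 one-step amino-acid pair types); columns
#' differing at 2–3 positions are excluded and tallied separately.  The
#' mutational opportunity of each pair type is the number of single-base
#' neighbor changes realizing it, summed over the alignment's codons
#' (averaged across the two sequences).  Each pair's rate per opportunity
#' is divided by the synonymous rate per opportunity, so a pair type
#' accepted at the neutral (synonymous) rate has scaled Ki = 1 —
#' equivalently, Ki is scaled such that Ka/Ks = 1 for neutral types.
#'
#' @param x an [ortholog_gene()] with a `codons` component holding
#'   exactly two species, or a length-2 named character vector of aligned
#'   codon sequences.
#' @param pairs_obj an [enumerate_one_step_pairs()] (default: standard
#'   code).
#' @param jc_correction apply a Jukes–Cantor multiple-hit correction to
#'   Ks (default `FALSE`: the estimator targets closely related pairs).
#' @param ks_warn warn when Ks exceeds this divergence (default 0.3),
#'   where multiple hits per codon stop being rare.
#' @return object of class `ki_spectrum`: list with `table` (data frame
#'   `pair`, `count`, `opportunity`, `rate`, `ki`, `rank` — K1..K75 in
#'   descending scaled rate, ties broken by pair name), `ks` (synonymous
#'   substitutions per synonymous site), `syn_count`, `syn_opportunity`,
#'   `multi_hit` (excluded columns), `undefined` (no synonymous signal),
#'   and `species`.
#' @export
estimate_ki <- function(x, pairs_obj = enumerate_one_step_pairs(),
                        jc_correction = FALSE, ks_warn = 0.3) {
  if (inherits(x, "ortholog_gene")) {
    if (is.null(x$codons)) stop("gene has no codon alignment")
    seqs <- x$codons
  } else seqs <- x
  if (length(seqs) != 2L)
    stop("Ki estimation needs exactly two aligned sequences")
  code <- pairs_obj$code
  c1 <- split_codons(toupper(seqs[[1L]]))
  c2 <- split_codons(toupper(seqs[[2L]]))
  if (length(c1) != length(c2)) stop("codon sequences differ in length")
  sense <- names(code)[code != "*"]
  ok <- c1 %in% sense & c2 %in% sense
  c1 <- c1[ok]; c2 <- c2[ok]
  if (!length(c1)) stop("no comparable codon columns")
  # opportunities (average of the two sequences' codon compositions)
  M <- codon_opportunity_matrix(pairs_obj)
  cnt <- (table(factor(c1, levels = sense)) +
          table(factor(c2, levels = sense))) / 2
  opp <- as.numeric(cnt) %*% M
  opp <- stats::setNames(as.numeric(opp), colnames(M))
  # observed single-hit differences
  ndiff <- (substr(c1, 1, 1) != substr(c2, 1, 1)) +
           (substr(c1, 2, 2) != substr(c2, 2, 2)) +
           (substr(c1, 3, 3) != substr(c2, 3, 3))
  one <- ndiff == 1L
  multi_hit <- sum(ndiff > 1L)
  a1 <- code[c1[one]]
  a2 <- code[c2[one]]
  syn_count <- sum(a1 == a2)
  lab <- pair_label(a1[a1 != a2], a2[a1 != a2])
  pair_counts <- table(factor(lab, levels = pairs_obj$pairs))
  syn_opp <- opp[["syn"]]
  syn_rate <- if (syn_opp > 0) syn_count / syn_opp else NA_real_
  undefined <- is.na(syn_rate) || syn_rate == 0
  if (undefined)
    warning("no synonymous divergence: scaled Ki undefined")
  # Ks per synonymous site (NG86-style sites = opportunities / 3)
  p_syn <- if (syn_opp > 0) syn_count / (syn_opp / 3) else NA_real_
  ks <- p_syn
  if (jc_correction && !is.na(p_syn) && p_syn < 3 / 4)
    ks <- -3 / 4 * log(1 - 4 / 3 * p_syn)
  if (!is.na(ks) && ks > ks_warn)
    warning(sprintf("Ks = %.3f exceeds %.2f: multiple hits are not rare; %s",
                    ks, ks_warn, "interpret the counting estimate cautiously"))
  pair_opp <- opp[pairs_obj$pairs]
  rate <- ifelse(pair_opp > 0, as.numeric(pair_counts) / pair_opp, NA_real_)
  ki <- if (undefined) rep(NA_real_, length(rate)) else rate / syn_rate
  tab <- data.frame(pair = pairs_obj$pairs,
                    count = as.integer(pair_counts),
                    opportunity = unname(pair_opp),
                    rate = unname(rate), ki = unname(ki),
                    stringsAsFactors = FALSE)
  ord <- order(-replace(tab$ki, is.na(tab$ki), -Inf), tab$pair)
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(nrow(tab))
  structure(list(table = tab, ks = ks, syn_count = syn_count,
                 syn_opportunity = unname(syn_opp),
                 multi_hit = multi_hit, undefined = undefined,
                 species = names(seqs)),
            class = "ki_spectrum")
}

#' @export
print.ki_spectrum <- function(x, ...) {
  cat(sprintf("<ki_spectrum> %s vs %s: Ks = %s, %d one-step pairs%s\n",
              x$species[1L], x$species[2L],
              format(x$ks, digits = 3), nrow(x$table),
              if (x$undefined) " [undefined: Ks = 0]" else ""))
  invisible(x)
}

#' Expected spectrum (universal index) from reference species pairs
#'
#' Computes, per one-step pair, the mean and standard deviation of the
#' scaled Ki across a panel of reference spectra (the protocol uses eight
#' reference species pairs).
#'
#' @param spectra list of [estimate_ki()] results (or data frames with
#'   `pair` and `ki`), at least 3.
#' @return data frame `pair`, `mean`, `sd` of class `universal_index`.
#' @export
universal_index <- function(spectra) {
  if (length(spectra) < 3L)
    stop("need at least 3 reference spectra to estimate a standard deviation")
  tabs <- lapply(spectra, function(s)
    if (inherits(s, "ki_spectrum")) s$table else s)
  pairs <- tabs[[1L]]$pair
  m <- vapply(tabs, function(t) t$ki[match(pairs, t$pair)],
              numeric(length(pairs)))
  out <- data.frame(pair = pairs,
                    mean = rowMeans(m, na.rm = TRUE),
                    sd = apply(m, 1L, stats::sd, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  class(out) <- c("universal_index", "data.frame")
  out
}

#' Read/write an expected-spectrum table
#'
#' Three-column TSV: `pair`, `mean`, `sd`.
#'
#' @param path TSV file.
#' @return `universal_index` data frame.
#' @export
read_universal_index <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("pair", "mean", "sd") %in% names(df)))
    stop("expected columns pair, mean, sd")
  if (any(df$sd <= 0)) stop("expected-spectrum SDs must be positive")
  class(df) <- c("universal_index", "data.frame")
  df
}

#' @rdname read_universal_index
#' @param index a `universal_index` data frame to write.
#' @export
write_universal_index <- function(index, path) {
  utils::write.table(index, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Score deviations of observed spectra from the expected spectrum
#'
#' For each focal taxon pair, `z = (observed Ki - expected mean) / SD`;
#' positive z means the exchange is accelerated relative to expectation.
#' The convergent set holds the pairs whose `|z|` exceeds the threshold
#' in every focal taxon pair.
#'
#' @param observed named list of [estimate_ki()] spectra (or of named
#'   numeric Ki vectors), one per focal taxon pair.
#' @param expected a [universal_index()] table.
#' @param threshold deviation threshold in SD units (default 2.5).
#' @return object of class `deviation_report`: list with `z` (data frame
#'   `pair` + one column per taxon pair), `convergent_pairs`, `threshold`.
#' @export
compute_deviations <- function(observed, expected, threshold = 2.5) {
  kis <- lapply(observed, function(o) {
    if (inherits(o, "ki_spectrum"))
      stats::setNames(o$table$ki, o$table$pair)
    else o
  })
  z <- vapply(kis, function(k)
    (k[expected$pair] - expected$mean) / expected$sd,
    numeric(nrow(expected)))
  z <- as.data.frame(z)
  if (!is.null(names(observed))) names(z) <- names(observed)
  deviation_report(cbind(data.frame(pair = expected$pair,
                                    stringsAsFactors = FALSE), z),
                   threshold = threshold)
}

#' Construct a deviation report from z-scores
#'
#' @param z data frame with a `pair` column and one numeric z column per
#'   focal taxon pair.
#' @param threshold SD threshold for the convergent set.
#' @return a `deviation_report` (see [compute_deviations()]).
#' @export
deviation_report <- function(z, threshold = 2.5) {
  stopifnot(is.data.frame(z), "pair" %in% names(z))
  zm <- as.matrix(z[, setdiff(names(z), "pair"), drop = FALSE])
  conv <- z$pair[apply(abs(zm) > threshold, 1L, all)]
  conv <- conv[!is.na(conv)]
  structure(list(z = z, convergent_pairs = conv, threshold = threshold),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf(
    "<deviation_report> %d pairs x %d taxon pairs; %d convergent at |z| > %.2g\n",
    nrow(x$z), ncol(x$z) - 1L, length(x$convergent_pairs), x$threshold))
  invisible(x)
}

#' Summary aggregates of a deviation report
#'
#' @param report a `deviation_report`.
#' @return list with `row_averages` (per-pair mean z across the focal
#'   taxon pairs, signed), `column_mean_abs` (per-taxon mean of absolute
#'   z), and `mean_abs_row_average` (mean of the absolute row averages).
#' @export
summarize_deviation_table <- function(report) {
  zm <- as.matrix(report$z[, setdiff(names(report$z), "pair"),
                           drop = FALSE])
  rows <- rowMeans(zm)
  names(rows) <- report$z$pair
  list(row_averages = rows,
       column_mean_abs = colMeans(abs(zm)),
       mean_abs_row_average = mean(abs(rows)))
}
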