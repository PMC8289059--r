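# Shared helpers: toy alignment builders and independent brute-force
# oracles against which the vectorized/pipelined implementations are
# checked.  The oracles deliberately re-state the rules in the plainest
# possible code and share nothing with the package internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build an ortholog gene from per-species state vectors (one letter per
# column).
toy_gene <- function(gene_id, ...) {
  cols <- list(...)
  seqs <- vapply(cols, paste, character(1), collapse = "")
  ortholog_gene(gene_id, seqs)
}

# Standard 7-species symmetric roles (3 clades, no extras).
toy_roles <- function() example_role_config(3L, 0L, 0L)

# Oracle for Step-I calling on a single column of a 3-clade symmetric
# design: states named F1..F3, C1..C3, OG.  Returns the derived states
# called (character(0) if none).
oracle_call_column <- function(states, direction = "focal") {
  miss <- function(x) x %in% c("-", "X")
  if (direction == "focal") {
    controls <- states[c("C1", "C2", "C3")]
    focals <- states[c("F1", "F2", "F3")]
  } else {
    controls <- states[c("F1", "F2", "F3")]
    focals <- states[c("C1", "C2", "C3")]
  }
  og <- states[["OG"]]
  if (miss(og)) return(character(0))
  if (any(miss(controls)) || any(controls != og)) return(character(0))
  foc <- focals[!miss(focals) & focals != og]
  if (length(foc) < 2L) return(character(0))
  tab <- table(foc)
  sort(names(tab)[tab >= 2L])
}

# Oracle recount of n (Step I) and n' (Step II) on a simulated tip
# matrix, using whole-matrix logical operations -- an independent path
# from the per-gene caller.  Assumes no missing data (simulated states).
oracle_noise_counts <- function(aa_mat, roles, gene_lengths, z = 2L) {
  og <- roles$species[roles$role == "outgroup"]
  fk <- roles$species[roles$role == "focal_key"]
  ck <- roles$species[roles$role == "control_key"]
  fx <- roles$species[roles$role == "focal_extra"]
  cx <- roles$species[roles$role == "control_extra"]
  anc <- aa_mat[og, ]
  cons <- rep(TRUE, ncol(aa_mat))
  for (sp in ck) cons <- cons & aa_mat[sp, ] == anc
  # shared derived state among >= 2 focal keys (any pair equal, != anc)
  pair_idx <- utils::combn(fk, 2L, simplify = FALSE)
  called <- rep(FALSE, ncol(aa_mat))
  derived <- matrix(NA_character_, length(pair_idx), ncol(aa_mat))
  for (i in seq_along(pair_idx)) {
    p <- pair_idx[[i]]
    hit <- cons & aa_mat[p[1L], ] == aa_mat[p[2L], ] & aa_mat[p[1L], ] != anc
    called <- called | hit
    derived[i, hit] <- aa_mat[p[1L], hit]
  }
  # Step-II survival per column: every derived state called at the
  # column must be carried by all focal extras and by no control extra
  surv <- rep(FALSE, ncol(aa_mat))
  for (i in seq_along(pair_idx)) {
    ok <- !is.na(derived[i, ])
    if (!any(ok)) next
    d <- derived[i, ]
    keep <- ok
    for (sp in fx) keep <- keep & !is.na(d) & aa_mat[sp, ] == d
    for (sp in cx) keep <- keep & !is.na(d) & aa_mat[sp, ] != d
    surv <- surv | keep
  }
  # chunk into genes (cycle lengths, drop trailing partial)
  total <- ncol(aa_mat)
  lens <- integer(0)
  repeat {
    nxt <- gene_lengths[length(lens) %% length(gene_lengths) + 1L]
    if (sum(lens) + nxt > total) break
    lens <- c(lens, nxt)
  }
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  n <- 0L; np <- 0L
  for (g in seq_along(lens)) {
    idx <- starts[g]:ends[g]
    if (sum(called[idx]) >= z) n <- n + 1L
    if (sum(surv[idx]) >= z) np <- np + 1L
  }
  list(n = n, n_prime = np)
}

# Oracle for the three usage-outlier criteria on one amino acid, given
# the pooled percentage vector, focal ids, relatives and raw counts.
oracle_flag_aa <- function(pool_vals, focal_ids, rel_of, counts_aa,
                           counts_total, extreme_fraction = 0.10,
                           alpha = 0.01, quantile_type = 7L) {
  foc <- pool_vals[focal_ids]
  q1 <- quantile(pool_vals, 0.25, type = quantile_type, names = FALSE)
  q3 <- quantile(pool_vals, 0.75, type = quantile_type, names = FALSE)
  dir <- if (all(foc > q3)) "over" else if (all(foc < q1)) "under" else "none"
  if (dir == "none") return("none")
  k <- ceiling(extreme_fraction * length(pool_vals))
  sorted <- sort(pool_vals, decreasing = (dir == "over"))
  cut <- sorted[k]
  in_extreme <- if (dir == "over") any(foc >= cut) else any(foc <= cut)
  if (!in_extreme) return("none")
  for (f in focal_ids) {
    r <- rel_of[[f]]
    more <- if (dir == "over") pool_vals[f] > pool_vals[r]
            else pool_vals[f] < pool_vals[r]
    if (!more) return("none")
    tab <- matrix(c(counts_aa[f], counts_total[f] - counts_aa[f],
                    counts_aa[r], counts_total[r] - counts_aa[r]),
                  2L, 2L, byrow = TRUE)
    st <- suppressWarnings(chisq.test(tab, correct = FALSE))
    if (!is.finite(st$p.value) || st$p.value >= alpha) return("none")
  }
  dir
}

# Exact hypergeometric one-sided tail for enrichment (disjoint margins).
oracle_hyper_tail <- function(a, set_total, bg_hits, bg_total) {
  white <- a + bg_hits
  black <- set_total + bg_total - white
  sum(dhyper(a:min(set_total, white), white, black, set_total))
}
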