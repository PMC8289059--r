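# Step I of CCS+: convergence at conservative sites on the largest
# symmetric phylogeny, with the empirical control.
#
# A column is conservative (direction = "focal") when every control key
# species carries the same non-missing state as the outgroup; the shared
# state is then taken as the ancestral state O.  A convergent call requires
# at least two focal key species to share the same non-missing derived
# state != O at a conservative column.  The control direction applies the
# identical rules with focal and control roles switched, giving the
# empirical noise level N against the focal count A.

#' Find conservative alignment columns
#'
#' @param gene an [ortholog_gene()].
#' @param roles a `species_roles` configuration.
#' @param direction `"focal"` (control keys + outgroup define conservatism)
#'   or `"control"` (roles switched).
#' @return integer vector of 1-based column indices.
#' @details Missing data (`-`/`X`) at the outgroup or at any conserving
#'   species disqualifies the column: conservatism is an assertion about
#'   every control, so absence of evidence fails it.
#' @export
find_conservative_sites <- function(gene, roles, direction = c("focal", "control")) {
  direction <- match.arg(direction)
  if (direction == "control") roles <- swap_roles(roles)
  og <- role_species(roles, "outgroup")
  ck <- role_species(roles, "control_key")
  need <- c(og, ck)
  absent <- setdiff(need, rownames(gene$aa))
  if (length(absent))
    stop(sprintf("gene '%s' lacks required species: %s",
                 gene$gene_id, paste(absent, collapse = ", ")))
  out_states <- gene$aa[og, ]
  ok <- !is_missing_aa(out_states)
  for (sp in ck) {
    st <- gene$aa[sp, ]
    ok <- ok & !is_missing_aa(st) & st == out_states
  }
  which(ok)
}

#' Call convergent sites (Step I)
#'
#' At each conservative column, every derived state shared by two or more
#' focal key species yields one call.  Focal species with missing data
#' neither support nor veto a call; if all focal keys share the derived
#' state the call simply has larger support.  Two derived states at one
#' column produce two rows but count once toward the per-gene site tally
#' (see [genes_with_min_sites()]).
#'
#' @inheritParams find_conservative_sites
#' @return data frame with columns `gene_id`, `column` (1-based),
#'   `ancestral`, `derived`, `supporters` (comma-joined species ids),
#'   `n_support`, `direction`.  Zero rows when nothing is called.
#' @export
call_site_convergence <- function(gene, roles, direction = c("focal", "control")) {
  direction <- match.arg(direction)
  work <- if (direction == "control") swap_roles(roles) else roles
  cols <- find_conservative_sites(gene, roles, direction)
  fk <- role_species(work, "focal_key")
  absent <- setdiff(fk, rownames(gene$aa))
  if (length(absent))
    stop(sprintf("gene '%s' lacks focal species: %s",
                 gene$gene_id, paste(absent, collapse = ", ")))
  og <- role_species(work, "outgroup")
  empty <- data.frame(gene_id = character(), column = integer(),
                      ancestral = character(), derived = character(),
                      supporters = character(), n_support = integer(),
                      direction = character(), stringsAsFactors = FALSE)
  if (!length(cols)) return(empty)
  fmat <- gene$aa[fk, cols, drop = FALSE]
  anc <- gene$aa[og, cols]
  res <- vector("list", length(cols))
  for (j in seq_along(cols)) {
    st <- fmat[, j]
    st <- st[!is_missing_aa(st) & st != anc[j]]
    if (length(st) < 2L) next
    tab <- table(st)
    shared <- names(tab)[tab >= 2L]
    if (!length(shared)) next
    res[[j]] <- data.frame(
      gene_id = gene$gene_id, column = cols[j], ancestral = anc[j],
      derived = shared,
      supporters = vapply(shared, function(d)
        paste(fk[!is.na(fmat[, j]) & fmat[, j] == d], collapse = ","),
        character(1)),
      n_support = as.integer(tab[shared]),
      direction = direction, stringsAsFactors = FALSE)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Call convergence over a set of genes
#'
#' @param genes list of [ortholog_gene()] objects.
#' @inheritParams find_conservative_sites
#' @return one data frame of calls (see [call_site_convergence()]).
#' @export
call_genes <- function(genes, roles, direction = c("focal", "control")) {
  direction <- match.arg(direction)
  out <- lapply(genes, call_site_convergence, roles = roles,
                direction = direction)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Genes carrying at least z convergent sites
#'
#' Sites are counted as distinct columns: two derived states at one column
#' count once.
#'
#' @param calls call data frame from [call_site_convergence()].
#' @param z minimum number of convergent sites per gene (default 2).
#' @return character vector of gene ids.
#' @export
genes_with_min_sites <- function(calls, z = 2L) {
  if (z < 1L) stop("z must be >= 1")
  if (is.null(calls) || nrow(calls) == 0L) return(character())
  n_sites <- tapply(calls$column, calls$gene_id,
                    function(x) length(unique(x)))
  sort(names(n_sites)[n_sites >= z])
}

#' Summarize Step I: A, N, S and P_true
#'
#' With A focal convergent genes and N control (noise) convergent genes,
#' the signal is S = A - N and the probability of true convergence is
#' P_true = S/A.  When the control exceeds the focal count the estimate is
#' clamped at 0 and flagged.
#'
#' @param focal_genes character vector (or count) of focal convergent genes.
#' @param control_genes character vector (or count) of control convergent
#'   genes.
#' @param z the per-gene minimum-site threshold used (recorded only).
#' @return object of class `step1_summary`: list with `A`, `N`, `S`,
#'   `P_true`, `z`, `warning_noise_exceeds_signal`, and the two gene lists
#'   when vectors were supplied.
#' @export
summarize_step1 <- function(focal_genes, control_genes, z = 2L) {
  A <- if (is.numeric(focal_genes)) as.numeric(focal_genes) else length(focal_genes)
  N <- if (is.numeric(control_genes)) as.numeric(control_genes) else length(control_genes)
  stopifnot(A >= 0, N >= 0)
  S <- A - N
  warn <- N > A
  P_true <- if (A == 0) 0 else max(0, S) / A
  if (warn) {
    warning("control count exceeds focal count; P_true clamped at 0")
    P_true <- 0
  }
  structure(list(
    A = A, N = N, S = S, P_true = P_true, z = z,
    warning_noise_exceeds_signal = warn,
    focal_gene_list = if (is.numeric(focal_genes)) NULL else focal_genes,
    control_gene_list = if (is.numeric(control_genes)) NULL else control_genes),
    class = "step1_summary")
}

#' @export
print.step1_summary <- function(x, ...) {
  cat(sprintf(
    "CCS+ Step I (z = %d): A = %g focal genes, N = %g control genes\n",
    x$z, x$A, x$N))
  cat(sprintf("  signal S = A - N = %g;  P_true = S/A = %.4f%s\n",
              x$S, x$P_true,
              if (x$warning_noise_exceeds_signal) " [noise > signal]" else ""))
  invisible(x)
}

#' Run Step I end-to-end on a gene set
#'
#' Calls both directions, applies the per-gene site threshold and returns
#' calls plus the summary.
#'
#' @param genes list of [ortholog_gene()] objects.
#' @param roles a `species_roles` configuration.
#' @param z minimum convergent sites per gene.
#' @return list with `focal_calls`, `control_calls`, `focal_genes`,
#'   `control_genes`, `summary` (a `step1_summary`).
#' @export
run_step1 <- function(genes, roles, z = 2L) {
  fc <- call_genes(genes, roles, "focal")
  cc <- call_genes(genes, roles, "control")
  fg <- genes_with_min_sites(fc, z)
  cg <- genes_with_min_sites(cc, z)
  list(focal_calls = fc, control_calls = cc,
       focal_genes = fg, control_genes = cg,
       summary = summarize_step1(fg, cg, z))
}
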