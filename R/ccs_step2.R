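# Step II of CCS+: re-filter Step-I calls on the full phylogeny and apply
# the simulated noise-retention correction.
#
# On the full phylogeny convergence is defined more stringently:
#   (i)  every added focal species must carry the same convergent state;
#   (ii) no added control species may carry it;
#   (iii) a gene must still hold at least z convergent sites.
# The surviving focal gene count A' is observed; the surviving noise is
# N' = N * q with q the retention rate estimated by neutral simulation
# (see estimate_noise_retention), giving P'_true = (A' - N')/A'.

#' Filter Step-I calls on the full phylogeny
#'
#' @param calls focal-direction call data frame from Step I.
#' @param genes list of [ortholog_gene()] objects including the extra
#'   species; must be indexable by `gene_id` (a named list or one whose
#'   elements carry matching `gene_id`s).
#' @param roles a `species_roles` configuration (the full phylogeny:
#'   includes `focal_extra`/`control_extra` species).
#' @param z minimum surviving convergent sites per gene (default 2).
#' @param direction direction the calls were made in; extras are drawn
#'   from the matching side (`focal_extra` supports, `control_extra`
#'   vetoes; switched for `"control"`).
#' @param strict_missing if `TRUE` (default) an added focal species with
#'   missing data at the call column removes the call: the species cannot
#'   be shown to carry the convergent state, and Step II is the maximal
#'   de-noising step.  If `FALSE`, missing extras are ignored.  Missing
#'   data in an added control never vetoes.
#' @return list with `surviving_calls` (data frame, plus a column
#'   `n_extras_evaluated`), `surviving_genes` (character vector).
#' @export
filter_full_phylogeny <- function(calls, genes, roles, z = 2L,
                                  direction = c("focal", "control"),
                                  strict_missing = TRUE) {
  direction <- match.arg(direction)
  work <- if (direction == "control") swap_roles(roles) else roles
  fx <- role_species(work, "focal_extra")
  cx <- role_species(work, "control_extra")
  if (is.null(names(genes)))
    names(genes) <- vapply(genes, function(g) g$gene_id, character(1))
  if (is.null(calls) || nrow(calls) == 0L)
    return(list(surviving_calls = calls, surviving_genes = character()))
  keep <- logical(nrow(calls))
  n_eval <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    g <- genes[[calls$gene_id[i]]]
    if (is.null(g)) stop("no alignment for gene ", calls$gene_id[i])
    j <- calls$column[i]
    d <- calls$derived[i]
    ok <- TRUE
    n <- 0L
    for (sp in fx) {
      st <- if (sp %in% rownames(g$aa)) g$aa[sp, j] else "-"
      if (is_missing_aa(st)) {
        if (strict_missing) ok <- FALSE
      } else {
        n <- n + 1L
        if (st != d) ok <- FALSE        # criterion (i)
      }
      if (!ok) break
    }
    if (ok) for (sp in intersect(cx, rownames(g$aa))) {
      st <- g$aa[sp, j]
      if (!is_missing_aa(st)) {
        n <- n + 1L
        if (st == d) { ok <- FALSE; break }  # criterion (ii)
      }
    }
    keep[i] <- ok
    n_eval[i] <- n
  }
  surv <- calls[keep, , drop = FALSE]
  surv$n_extras_evaluated <- n_eval[keep]
  rownames(surv) <- NULL
  gs <- genes_with_min_sites(surv, z)          # criterion (iii)
  surv <- surv[surv$gene_id %in% gs, , drop = FALSE]
  rownames(surv) <- NULL
  list(surviving_calls = surv, surviving_genes = gs)
}

#' Summarize Step II: A', N', q and P'_true
#'
#' @param A_prime surviving focal gene count (or gene id vector).
#' @param N Step-I control gene count.
#' @param q noise retention rate in `[0, 1]` (from
#'   [estimate_noise_retention()] or supplied directly).
#' @param z the per-gene minimum-site threshold used (recorded only).
#' @return object of class `step2_summary`: list with `A_prime`, `N`, `q`,
#'   `N_prime = N * q`, `S_prime`, `P_prime_true` (clamped into `[0, 1]`
#'   with a flag when noise exceeds the observed count or A' = 0).
#' @export
summarize_step2 <- function(A_prime, N, q, z = 2L) {
  Ap <- if (is.numeric(A_prime)) as.numeric(A_prime) else length(A_prime)
  stopifnot(Ap >= 0, N >= 0, q >= 0, q <= 1)
  Np <- N * q
  Sp <- Ap - Np
  warn <- FALSE
  if (Ap == 0) {
    warn <- TRUE
    P <- 0
  } else if (Np > Ap) {
    warning("retained noise N' exceeds A'; P'_true clamped at 0")
    warn <- TRUE
    P <- 0
  } else {
    P <- Sp / Ap
  }
  structure(list(
    A_prime = Ap, N = N, q = q, N_prime = Np, S_prime = Sp,
    P_prime_true = P, z = z, warning_flag = warn),
    class = "step2_summary")
}

#' @export
print.step2_summary <- function(x, ...) {
  cat(sprintf(
    "CCS+ Step II (z = %d): A' = %g, N = %g, q = %.4g => N' = %.3g\n",
    x$z, x$A_prime, x$N, x$q, x$N_prime))
  cat(sprintf("  P'_true = (A' - N')/A' = %.3f%s\n", x$P_prime_true,
              if (x$warning_flag) " [flagged]" else ""))
  invisible(x)
}

#' Run Step I + Step II end-to-end
#'
#' @param genes list of [ortholog_gene()] objects (full phylogeny).
#' @param roles a `species_roles` configuration with extra species.
#' @param q noise retention rate; pass 1 to reproduce Step I exactly when
#'   no extras exist, or the value from [estimate_noise_retention()].
#' @param z minimum convergent sites per gene.
#' @param strict_missing see [filter_full_phylogeny()].
#' @return list with the Step-I result (`step1`), the surviving calls and
#'   genes, and the `step2_summary`.
#' @export
run_step2 <- function(genes, roles, q, z = 2L, strict_missing = TRUE) {
  s1 <- run_step1(genes, roles, z)
  keep <- s1$focal_calls[s1$focal_calls$gene_id %in% s1$focal_genes, ,
                         drop = FALSE]
  flt <- filter_full_phylogeny(keep, genes, roles, z = z,
                               direction = "focal",
                               strict_missing = strict_missing)
  list(step1 = s1,
       surviving_calls = flt$surviving_calls,
       surviving_genes = flt$surviving_genes,
       summary = summarize_step2(flt$surviving_genes, s1$summary$N, q, z))
}
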