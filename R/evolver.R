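# Amino-acid sequence simulation along a phylogeny under a reversible
# empirical model (LG by default), and the Step-I -> Step-II noise
# retention rate q = n'/n estimated on purely neutral simulated data.

#' Build a scaled amino-acid rate model
#'
#' Constructs the generator Q of a general time-reversible amino-acid
#' chain from a symmetric exchangeability matrix `s` and equilibrium
#' frequencies `pi`: `Q[i,j] = s[i,j] * pi[j]`, the diagonal set for zero
#' row sums, and the whole matrix scaled so the expected number of
#' substitutions per site per unit branch length is 1
#' (`-sum(pi * diag(Q)) = 1`).  The spectral decomposition of the
#' pi-symmetrized generator is cached so transition matrices
#' `P(t) = expm(Q t)` are a single matrix product per branch.
#'
#' @param exchangeabilities symmetric, nonnegative 20x20 matrix (diagonal
#'   ignored), rows/cols in the order `AA_LETTERS` (A R N D C Q E G H I L
#'   K M F P S T W Y V).
#' @param freqs 20-vector of equilibrium frequencies, all positive,
#'   summing to 1 within 1e-8.
#' @return object of class `aa_rate_model`: list with `s`, `pi`, `Q` and
#'   the cached eigensystem.
#' @export
aa_rate_model <- function(exchangeabilities, freqs) {
  s <- as.matrix(exchangeabilities)
  stopifnot(dim(s) == c(20L, 20L), length(freqs) == 20L)
  if (any(s < 0)) stop("exchangeabilities must be nonnegative")
  if (max(abs(s - t(s))) > 1e-10) stop("exchangeability matrix must be symmetric")
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  if (any(freqs <= 0))
    stop("degenerate stationary distribution: all frequencies must be > 0")
  pi <- freqs / sum(freqs)
  diag(s) <- 0
  Q <- s * rep(pi, each = 20L)          # Q[i,j] = s[i,j] * pi[j]
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (rate <= 0) stop("rate matrix has zero total rate")
  Q <- Q / rate
  dimnames(Q) <- list(AA_LETTERS, AA_LETTERS)
  # reversible: D^(1/2) Q D^(-1/2) is symmetric; eigendecompose once
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(
    s = s, pi = stats::setNames(pi, AA_LETTERS), Q = Q,
    eig_values = eig$values,
    eig_left = eig$vectors * (1 / sq),       # D^(-1/2) U
    eig_right = t(eig$vectors * sq)),        # U' D^(1/2)
    class = "aa_rate_model")
}

#' @export
print.aa_rate_model <- function(x, ...) {
  cat("<aa_rate_model> 20-state reversible generator, unit expected rate\n")
  invisible(x)
}

#' Transition probability matrix P(t) = expm(Q t)
#'
#' @param model an [aa_rate_model()].
#' @param t branch length (expected substitutions per site).
#' @return 20x20 stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(t >= 0, is.finite(t))
  P <- model$eig_left %*% (exp(model$eig_values * t) * model$eig_right)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(model$Q)
  P
}

#' The LG amino-acid model
#'
#' Exchangeabilities and equilibrium frequencies of the LG empirical
#' matrix, taken from the `phangorn` model library, assembled into a
#' scaled [aa_rate_model()].
#'
#' @param freqs optional replacement equilibrium frequencies (e.g.
#'   empirical `+F` frequencies estimated from data); defaults to the
#'   model's own.
#' @return an `aa_rate_model`.
#' @export
lg_model <- function(freqs = NULL) {
  lg <- get(".LG", envir = environment(phangorn::pml))
  s <- matrix(0, 20L, 20L)
  s[lower.tri(s)] <- lg$Q
  s <- s + t(s)
  pi <- if (is.null(freqs)) unname(lg$bf) else freqs
  aa_rate_model(s, pi)
}

#' A 20-state symmetric (Jukes-Cantor-like) model
#'
#' All exchangeabilities equal, uniform frequencies: every off-diagonal
#' transition rate identical.  Useful for closed-form checks — the
#' expected fraction of differing sites after total path length t is
#' `(19/20) * (1 - exp(-20 t / 19))`.
#'
#' @return an `aa_rate_model`.
#' @export
uniform_aa_model <- function() {
  s <- matrix(1, 20L, 20L)
  aa_rate_model(s, rep(1 / 20, 20L))
}

#' Read an empirical rate matrix in the PAML text layout
#'
#' The standard layout of empirical amino-acid model files: 19 rows of
#' lower-triangular exchangeabilities (row k holding k entries, amino
#' acids in the order A R N D C Q E G H I L K M F P S T W Y V), followed
#' by the 20 equilibrium frequencies.
#'
#' @param path text file.
#' @return an [aa_rate_model()].
#' @export
read_paml_rates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- readLines(path)
  txt <- txt[!grepl("^\\s*(#|$)", txt)]
  nums <- as.numeric(unlist(strsplit(paste(txt, collapse = " "), "\\s+")))
  nums <- nums[!is.na(nums)]
  if (length(nums) < 210L)
    stop("expected 190 exchangeabilities + 20 frequencies, found ",
         length(nums), " numbers")
  s <- matrix(0, 20L, 20L)
  k <- 1L
  for (i in 2:20) for (j in 1:(i - 1)) {
    s[i, j] <- nums[k]
    k <- k + 1L
  }
  s <- s + t(s)
  aa_rate_model(s, nums[191:210])
}

#' Simulate amino-acid sites along a phylogeny
#'
#' The root sequence is drawn from the model's equilibrium frequencies;
#' each branch applies `P(t) = expm(Q t)` independently per site.
#'
#' @param tree an [ape::phylo] tree with branch lengths (substitutions
#'   per site); validated with [validate_tree()].
#' @param model an [aa_rate_model()].
#' @param n_sites number of independent sites.
#' @param seed optional integer seed (local to this call).
#' @param return_internal keep internal-node sequences (default `FALSE`;
#'   they roughly double memory).
#' @return object of class `simulated_alignment`: list with `tips`
#'   (integer matrix species x sites, values 1..20 indexing
#'   `AA_LETTERS`), optionally `nodes`, plus `tree` and `model`.
#' @export
simulate_along_tree <- function(tree, model, n_sites, seed = NULL,
                                return_internal = FALSE) {
  validate_tree(tree)
  stopifnot(inherits(model, "aa_rate_model"), n_sites >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n_sites <- as.integer(n_sites)
  tr <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tr$tip.label)
  n_node <- tr$Nnode
  root <- n_tip + 1L
  states <- vector("list", n_tip + n_node)
  states[[root]] <- sample.int(20L, n_sites, replace = TRUE, prob = model$pi)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]
    chd <- tr$edge[e, 2L]
    P <- transition_matrix(model, tr$edge.length[e])
    ps <- states[[par]]
    cs <- integer(n_sites)
    for (k in 1:20) {
      idx <- which(ps == k)
      if (length(idx))
        cs[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = P[k, ])
    }
    states[[chd]] <- cs
    # free internal parents once all children are done (cladewise order
    # guarantees children follow their parent)
    if (!return_internal && par != root && e < nrow(tr$edge) &&
        !par %in% tr$edge[(e + 1L):nrow(tr$edge), 1L])
      states[[par]] <- integer(0)
  }
  tips <- do.call(rbind, states[seq_len(n_tip)])
  rownames(tips) <- tr$tip.label
  out <- list(tips = tips, tree = tree, model = model)
  if (return_internal) {
    nodes <- do.call(rbind, states[root:(n_tip + n_node)])
    rownames(nodes) <- paste0("node", root:(n_tip + n_node))
    out$nodes <- nodes
  }
  structure(out, class = "simulated_alignment")
}

#' Simulated states as an amino-acid character matrix
#' @param sim a `simulated_alignment`.
#' @return character matrix (species x sites) of amino-acid letters.
#' @export
as_aa_matrix <- function(sim) {
  m <- matrix(AA_LETTERS[sim$tips], nrow = nrow(sim$tips),
              dimnames = list(rownames(sim$tips), NULL))
  m
}

#' Chunk a simulated alignment into ortholog genes
#'
#' Cycles `gene_lengths` in order until the sites are consumed; a trailing
#' partial gene is discarded.
#'
#' @param aa_mat character matrix species x sites.
#' @param gene_lengths integer vector of gene lengths (amino acids).
#' @param prefix gene-id prefix.
#' @return named list of [ortholog_gene()] objects.
#' @export
chunk_into_genes <- function(aa_mat, gene_lengths, prefix = "simgene") {
  stopifnot(all(gene_lengths >= 1))
  total <- ncol(aa_mat)
  lens <- integer(0)
  while (sum(lens) + gene_lengths[length(lens) %% length(gene_lengths) + 1L] <= total)
    lens <- c(lens, gene_lengths[length(lens) %% length(gene_lengths) + 1L])
  if (!length(lens)) stop("not enough sites for a single gene")
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  genes <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    id <- sprintf("%s%05d", prefix, i)
    genes[[i]] <- structure(
      list(gene_id = id,
           aa = aa_mat[, starts[i]:ends[i], drop = FALSE]),
      class = "ortholog_gene")
    names(genes)[i] <- id
  }
  genes
}

#' Estimate the Step-II noise retention rate q by neutral simulation
#'
#' Simulates `total_sites` amino-acid sites along the tree under the model
#' (no selection, hence every convergence call is noise), assembles them
#' into genes by cycling `gene_lengths`, runs the Step-I caller and the
#' Step-II full-phylogeny filter with the same z, and reports
#' `q = n' / n` where n and n' are the simulated noise gene counts in the
#' two steps.
#'
#' @param tree phylogeny covering every species in `roles`.
#' @param model an [aa_rate_model()] (default [lg_model()]).
#' @param roles a `species_roles` configuration.
#' @param gene_lengths per-gene lengths used to assemble sites into genes.
#' @param total_sites total simulated sites (the reference protocol uses
#'   1e8; scale down for exploratory runs — the standard error of q grows
#'   accordingly).
#' @param z minimum convergent sites per gene.
#' @param seed integer seed.
#' @param strict_missing passed to [filter_full_phylogeny()] (simulated
#'   data have no missing states, so this is inert unless tips are absent).
#' @return object of class `noise_retention`: list with `n`, `n_prime`,
#'   `q` (NA and flagged when n = 0), plus the settings.
#' @export
estimate_noise_retention <- function(tree, model = lg_model(), roles,
                                     gene_lengths, total_sites = 1e6,
                                     z = 2L, seed = NULL,
                                     strict_missing = TRUE) {
  need <- roles$species
  absent <- setdiff(need, tree$tip.label)
  if (length(absent))
    stop("tree lacks tips for: ", paste(absent, collapse = ", "))
  sim <- simulate_along_tree(tree, model, total_sites, seed = seed)
  genes <- chunk_into_genes(as_aa_matrix(sim), gene_lengths)
  calls <- call_genes(genes, roles, "focal")
  n_genes <- genes_with_min_sites(calls, z)
  keep <- calls[calls$gene_id %in% n_genes, , drop = FALSE]
  flt <- filter_full_phylogeny(keep, genes, roles, z = z,
                               direction = "focal",
                               strict_missing = strict_missing)
  n <- length(n_genes)
  np <- length(flt$surviving_genes)
  structure(list(
    n = n, n_prime = np,
    q = if (n == 0) NA_real_ else np / n,
    undefined = n == 0,
    total_sites = as.integer(total_sites), z = z, seed = seed,
    n_genes_simulated = length(genes)),
    class = "noise_retention")
}

#' @export
print.noise_retention <- function(x, ...) {
  cat(sprintf(
    "noise retention: n = %d, n' = %d, q = %s (%d genes, %g sites, z = %d)\n",
    x$n, x$n_prime,
    if (x$undefined) "undefined (n = 0; raise total_sites)"
    else format(x$q, digits = 4),
    x$n_genes_simulated, x$total_sites, x$z))
  invisible(x)
}
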