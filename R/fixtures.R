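# Synthetic-data generators: planted convergent sites on a symmetric
# phylogeny, usage-shifted proteomes, and codon pairs evolved under
# stated one-step exchange rates.  Every generator is reproducible from
# (parameters, seed) and returns a truth table sufficient for exact
# precision/recall of the matching detection stage.

#' A symmetric example role configuration
#'
#' Builds the symmetric focal/control design: `n_clades` clades each
#' holding one focal key paired with one control key (plus optional extra
#' species per side), and a single outgroup.  Species ids are `F1..`,
#' `Fx1.1..` (focal extras), `C1..`, `Cx1.1..`, `OG`.
#'
#' @param n_clades number of focal/control pairs (>= 2).
#' @param n_focal_extra,n_control_extra extra species per clade side.
#' @return a `species_roles` configuration.
#' @export
example_role_config <- function(n_clades = 3L, n_focal_extra = 0L,
                                n_control_extra = 0L) {
  stopifnot(n_clades >= 2L)
  rows <- list()
  for (i in seq_len(n_clades)) {
    cl <- paste0("clade", i)
    rows[[length(rows) + 1L]] <- data.frame(
      species = paste0("F", i), role = "focal_key", clade = cl,
      closest_relative = paste0("C", i), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      species = paste0("C", i), role = "control_key", clade = cl,
      closest_relative = paste0("F", i), stringsAsFactors = FALSE)
    for (j in seq_len(n_focal_extra))
      rows[[length(rows) + 1L]] <- data.frame(
        species = sprintf("Fx%d.%d", i, j), role = "focal_extra",
        clade = cl, closest_relative = NA_character_,
        stringsAsFactors = FALSE)
    for (j in seq_len(n_control_extra))
      rows[[length(rows) + 1L]] <- data.frame(
        species = sprintf("Cx%d.%d", i, j), role = "control_extra",
        clade = cl, closest_relative = NA_character_,
        stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    species = "OG", role = "outgroup", clade = "outgroup",
    closest_relative = NA_character_, stringsAsFactors = FALSE)
  species_roles(do.call(rbind, rows))
}

#' A phylogeny matching an example role configuration
#'
#' Deep, symmetric clades: within each clade the focal and control key
#' species split near the root of the clade (mimicking an ancient habitat
#' shift), and extra species attach close to their key species so they
#' share most of its history.
#'
#' @param roles a configuration from [example_role_config()].
#' @param key_len branch length from the clade node to each key species.
#' @param extra_len terminal branch of extra species (their stem attaches
#'   at `key_len - extra_len` along the key branch).
#' @param clade_len root-to-clade branch length.
#' @param outgroup_len root-to-outgroup branch length.
#' @return an [ape::phylo] tree with branch lengths.
#' @export
example_tree <- function(roles, key_len = 0.4, extra_len = 0.15,
                         clade_len = 0.3, outgroup_len = 0.6) {
  stopifnot(extra_len < key_len)
  clades <- unique(roles$clade[roles$role == "focal_key"])
  side <- function(key, extras) {
    if (!length(extras))
      return(sprintf("%s:%g", key, key_len))
    # key and its extras form a comb near the tip
    stem <- key_len - extra_len
    tip <- sprintf("%s:%g", key, extra_len)
    for (e in extras)
      tip <- sprintf("(%s,%s:%g):0", tip, e, extra_len)
    sprintf("%s:%g", tip, stem)
  }
  parts <- vapply(clades, function(cl) {
    in_cl <- roles[roles$clade == cl, ]
    f <- side(in_cl$species[in_cl$role == "focal_key"],
              in_cl$species[in_cl$role == "focal_extra"])
    c_ <- side(in_cl$species[in_cl$role == "control_key"],
               in_cl$species[in_cl$role == "control_extra"])
    sprintf("(%s,%s):%g", f, c_, clade_len)
  }, character(1))
  nwk <- sprintf("(%s,%s:%g);", paste(parts, collapse = ","),
                 role_species(roles, "outgroup"), outgroup_len)
  validate_tree(ape::read.tree(text = nwk))
}

#' Generate a dataset with planted convergent sites
#'
#' Simulates neutral background alignments along the tree, then plants
#' convergence post hoc: in each signal gene, randomly chosen columns
#' that are conservative by construction get every focal species (keys
#' and extras) replaced by one common derived state.  Added control
#' species optionally receive the derived state (a homoplasy) at rate
#' `homoplasy_rate` per planted site, which Step II must remove.
#'
#' @param roles a `species_roles` configuration.
#' @param tree phylogeny covering the role species (default
#'   [example_tree()]).
#' @param model an [aa_rate_model()] (default [lg_model()]).
#' @param n_genes number of genes.
#' @param gene_length columns per gene (single value or vector cycled).
#' @param frac_signal fraction of genes carrying planted convergence.
#' @param sites_per_gene planted convergent sites per signal gene.
#' @param homoplasy_rate probability that one added control species also
#'   receives the derived state at a planted site.
#' @param seed integer seed.
#' @return list with `genes` (named list of [ortholog_gene()]), `roles`,
#'   `tree`, `truth` (data frame `gene_id`, `column`, `ancestral`,
#'   `derived`, `homoplasy`), `signal_genes`.
#' @export
make_planted_dataset <- function(roles, tree = example_tree(roles),
                                 model = lg_model(), n_genes = 50L,
                                 gene_length = 150L, frac_signal = 0.2,
                                 sites_per_gene = 2L,
                                 homoplasy_rate = 0, seed = NULL) {
  stopifnot(frac_signal >= 0, frac_signal <= 1,
            homoplasy_rate >= 0, homoplasy_rate <= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  lens <- rep_len(gene_length, n_genes)
  sim <- simulate_along_tree(tree, model, sum(lens))
  genes <- chunk_into_genes(as_aa_matrix(sim), lens, prefix = "gene")
  n_signal <- round(frac_signal * n_genes)
  signal <- sort(sample(names(genes), n_signal))
  fk <- role_species(roles, "focal_key")
  fx <- role_species(roles, "focal_extra")
  cx <- role_species(roles, "control_extra")
  og <- role_species(roles, "outgroup")
  truth <- list()
  for (gid in signal) {
    g <- genes[[gid]]
    cons <- find_conservative_sites(g, roles, "focal")
    # avoid columns that would already be called, keep truth exact
    if (length(cons) < sites_per_gene)
      stop("gene too short to plant ", sites_per_gene, " conservative sites")
    cols <- sort(sample(cons, sites_per_gene))
    for (j in cols) {
      anc <- g$aa[og, j]
      derived <- sample(setdiff(AA_LETTERS, anc), 1L)
      g$aa[c(fk, fx), j] <- derived
      hom <- FALSE
      if (length(cx) && homoplasy_rate > 0 &&
          stats::runif(1) < homoplasy_rate) {
        g$aa[sample(cx, 1L), j] <- derived
        hom <- TRUE
      }
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = gid, column = j, ancestral = anc, derived = derived,
        homoplasy = hom, stringsAsFactors = FALSE)
    }
    genes[[gid]] <- g
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), column = integer(),
               ancestral = character(), derived = character(),
               homoplasy = logical(), stringsAsFactors = FALSE)
  list(genes = genes, roles = roles, tree = tree, truth = truth,
       signal_genes = signal)
}

# Dirichlet draw around a base composition; conc controls tightness
rdirichlet1 <- function(base, conc) {
  g <- stats::rgamma(length(base), shape = base * conc, rate = 1)
  g / sum(g)
}

#' Generate usage-shifted proteomes
#'
#' Reference proteomes are sampled i.i.d. from compositions jittered
#' around a plant-like base (the LG equilibrium frequencies); focal
#' proteomes use the base composition with `delta`-shifted usage on the
#' chosen amino acids (multiplicative `1 + delta` up, `1 - delta` down,
#' renormalized).  Each focal genome is paired with one reference genome
#' as its closest relative.
#'
#' @param n_reference reference panel size (default 54).
#' @param n_focal focal genomes (default 3).
#' @param aas_up,aas_down amino acids shifted up/down (defaults: 4 up,
#'   5 down).
#' @param delta relative shift (0 = null data).
#' @param proteome_residues residues per proteome.
#' @param protein_length residues per protein sequence.
#' @param concentration Dirichlet concentration scale of between-species
#'   composition jitter (larger = tighter panel).
#' @param seed integer seed.
#' @return list with `focal` (named list of sequence vectors),
#'   `reference` (same), `pairs` (focal id -> relative id),
#'   `truth` (data frame `aa`, `direction`), and the profile lists
#'   `focal_profiles`, `reference_profiles`.
#' @export
make_usage_dataset <- function(n_reference = 54L, n_focal = 3L,
                               aas_up = c("G", "P", "R", "A"),
                               aas_down = c("I", "F", "M", "L", "N"),
                               delta = 0.15,
                               proteome_residues = 2e4L,
                               protein_length = 400L,
                               concentration = 5000,
                               seed = NULL) {
  stopifnot(delta >= 0, delta < 1,
            !anyDuplicated(c(aas_up, aas_down)))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  base <- lg_model()$pi
  shifted <- base
  shifted[aas_up] <- shifted[aas_up] * (1 + delta)
  shifted[aas_down] <- shifted[aas_down] * (1 - delta)
  shifted <- shifted / sum(shifted)
  sample_proteome <- function(comp, id) {
    res <- sample(AA_LETTERS, proteome_residues, replace = TRUE, prob = comp)
    n_prot <- ceiling(proteome_residues / protein_length)
    idx <- rep(seq_len(n_prot), each = protein_length)[seq_along(res)]
    seqs <- vapply(split(res, idx), paste, character(1), collapse = "")
    names(seqs) <- sprintf("%s_p%04d", id, seq_along(seqs))
    seqs
  }
  reference <- list()
  for (i in seq_len(n_reference)) {
    id <- sprintf("ref%02d", i)
    reference[[id]] <- sample_proteome(rdirichlet1(base, concentration), id)
  }
  focal <- list()
  for (i in seq_len(n_focal)) {
    id <- sprintf("focal%d", i)
    focal[[id]] <- sample_proteome(rdirichlet1(shifted, concentration), id)
  }
  pairs <- stats::setNames(names(reference)[seq_len(n_focal)], names(focal))
  truth <- if (delta > 0) data.frame(
    aa = c(aas_up, aas_down),
    direction = rep(c("over", "under"), c(length(aas_up), length(aas_down))),
    stringsAsFactors = FALSE)
  else data.frame(aa = character(), direction = character(),
                  stringsAsFactors = FALSE)
  list(focal = focal, reference = reference, pairs = pairs, truth = truth,
       focal_profiles = lapply(names(focal), function(id)
         compute_composition(focal[[id]], species = id)),
       reference_profiles = lapply(names(reference), function(id)
         compute_composition(reference[[id]], species = id)))
}

#' A fixed example one-step exchange-rate spectrum
#'
#' A deterministic decreasing spectrum over the 75 one-step pairs
#' (geometric decay from 3 down to 0.05 in the pairs' alphabetical
#' order), used as a stand-in expected spectrum for recovery tests; it is
#' synthetic and carries no empirical claim.
#'
#' @param pairs_obj an [enumerate_one_step_pairs()].
#' @return named numeric vector of 75 relative rates.
#' @export
example_ki_spectrum <- function(pairs_obj = enumerate_one_step_pairs()) {
  p <- pairs_obj$pairs
  stats::setNames(exp(seq(log(3), log(0.05), length.out = length(p))), p)
}

#' Simulate a pairwise codon alignment under stated exchange rates
#'
#' Two sequences evolve from a common uniform-sense-codon ancestor under
#' a symmetric codon chain: synonymous single-base changes at rate 1 and
#' each one-step nonsynonymous pair type at its stated rate relative to
#' synonymous; 2-3-base jumps and stop codons have rate 0.  The truth Ki
#' of a pair type is therefore exactly its stated rate.
#'
#' @param pair_rates named numeric vector over the 75 one-step pairs
#'   (relative to the synonymous rate); defaults to all 1 (strict
#'   neutrality).
#' @param ks_target target synonymous divergence per synonymous site
#'   between the two sequences.
#' @param n_codons number of codons.
#' @param seed integer seed.
#' @param pairs_obj an [enumerate_one_step_pairs()].
#' @return list with `seqs` (named length-2 character vector of codon
#'   sequences), `truth` (data frame `pair`, `ki_true`), `ks_target`.
#' @export
simulate_codon_pair <- function(pair_rates = NULL, ks_target = 0.15,
                                n_codons = 1e4L, seed = NULL,
                                pairs_obj = enumerate_one_step_pairs()) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (is.null(pair_rates))
    pair_rates <- stats::setNames(rep(1, length(pairs_obj$pairs)),
                                  pairs_obj$pairs)
  if (!all(pairs_obj$pairs %in% names(pair_rates)))
    stop("pair_rates must cover all one-step pairs")
  if (any(pair_rates < 0)) stop("rates must be nonnegative")
  code <- pairs_obj$code
  sense <- names(code)[code != "*"]
  ns <- length(sense)
  Q <- matrix(0, ns, ns, dimnames = list(sense, sense))
  bases <- c("A", "C", "G", "T")
  for (cd in sense) for (p in 1:3) for (b in bases) {
    if (substr(cd, p, p) == b) next
    nb <- cd
    substr(nb, p, p) <- b
    if (code[[nb]] == "*") next
    Q[cd, nb] <- if (code[[cd]] == code[[nb]]) 1
                 else pair_rates[[pair_label(code[[cd]], code[[nb]])]]
  }
  diag(Q) <- -rowSums(Q)
  # symmetric generator: uniform stationary distribution over sense codons
  eig <- eigen(Q, symmetric = TRUE)
  # per-branch time: synonymous changes accrue at ~1 per synonymous
  # mutational target per unit time, so Ks (per site, = 3x per target)
  # reaches ks_target at total path ks_target / 3
  t_branch <- ks_target / 6
  P <- eig$vectors %*% (exp(eig$values * t_branch) * t(eig$vectors))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  anc <- sample.int(ns, n_codons, replace = TRUE)
  evolve <- function(s) {
    out <- integer(length(s))
    for (k in seq_len(ns)) {
      idx <- which(s == k)
      if (length(idx))
        out[idx] <- sample.int(ns, length(idx), replace = TRUE, prob = P[k, ])
    }
    out
  }
  s1 <- evolve(anc)
  s2 <- evolve(anc)
  seqs <- c(sp1 = paste(sense[s1], collapse = ""),
            sp2 = paste(sense[s2], collapse = ""))
  list(seqs = seqs,
       truth = data.frame(pair = pairs_obj$pairs,
                          ki_true = unname(pair_rates[pairs_obj$pairs]),
                          stringsAsFactors = FALSE),
       ks_target = ks_target)
}
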