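# Data model and file I/O: aligned ortholog genes, species-role
# configurations, phylogenies, annotation tables and report writers.

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
MISSING_CHARS <- c("-", "X")
ROLE_LEVELS <- c("focal_key", "focal_extra", "control_key",
                 "control_extra", "outgroup")

#' Is an amino-acid state missing?
#'
#' Gap (`-`) and unknown (`X`) are both treated as missing data throughout
#' the package; any site-level rule sees them as "no information", never as
#' a 21st state.
#'
#' @param x character vector of single-letter amino-acid states.
#' @return logical vector.
#' @export
is_missing_aa <- function(x) x %in% MISSING_CHARS

#' Construct an aligned ortholog gene
#'
#' @param gene_id single gene identifier.
#' @param seqs named character vector of aligned amino-acid sequences
#'   (names are species ids; equal lengths; alphabet = 20 amino acids plus
#'   `-` and `X`).
#' @param codons optional named character vector of aligned codon
#'   sequences; each must be exactly 3x the amino-acid length.
#' @return an object of class `ortholog_gene`: a list with `gene_id`,
#'   `aa` (species x column character matrix) and optionally `codons`.
#' @export
ortholog_gene <- function(gene_id, seqs, codons = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique species ids as names")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- names(seqs)[lens != lens[1L]]
    stop(sprintf("ragged alignment in gene '%s': species %s differ in length",
                 gene_id, paste(bad, collapse = ", ")))
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  ok <- mat %in% c(AA_LETTERS, MISSING_CHARS)
  if (!all(ok)) {
    idx <- which(!ok)[1L]
    pos <- arrayInd(idx, dim(mat))
    stop(sprintf(
      "illegal amino-acid character '%s' in gene '%s', species '%s', column %d",
      mat[idx], gene_id, rownames(mat)[pos[1L]], pos[2L]))
  }
  obj <- list(gene_id = gene_id, aa = mat)
  if (!is.null(codons)) {
    if (!setequal(names(codons), names(seqs)))
      stop("codon sequences must cover the same species as the amino acids")
    codons <- codons[rownames(mat)]
    if (any(nchar(codons) != 3L * ncol(mat)))
      stop(sprintf("gene '%s': codon length must be 3x amino-acid length",
                   gene_id))
    obj$codons <- codons
  }
  structure(obj, class = "ortholog_gene")
}

#' @export
print.ortholog_gene <- function(x, ...) {
  cat(sprintf("<ortholog_gene> %s: %d species x %d columns%s\n",
              x$gene_id, nrow(x$aa), ncol(x$aa),
              if (is.null(x$codons)) "" else " (+codons)"))
  invisible(x)
}

#' Number of alignment columns
#' @param gene an `ortholog_gene`.
#' @return integer column count.
#' @export
gene_length <- function(gene) ncol(gene$aa)

#' Read an aligned amino-acid FASTA as an ortholog gene
#'
#' Sequence ids are taken verbatim as species ids (text after the first
#' whitespace in a FASTA header is dropped).
#'
#' @param path FASTA file of aligned amino-acid sequences.
#' @param gene_id gene identifier; defaults to the file name without
#'   extension.
#' @return an [ortholog_gene()].
#' @export
read_alignment <- function(path, gene_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(gene_id))
    gene_id <- sub("\\.[^.]*$", "", basename(path))
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  ortholog_gene(gene_id, seqs)
}

#' Read an aligned codon FASTA
#'
#' Validates a nucleotide alphabet (ACGT, N, -) and a length divisible
#' by 3; the translated amino acids are attached so the object can be used
#' by the site-convergence callers as well.
#'
#' @inheritParams read_alignment
#' @return an [ortholog_gene()] with a `codons` component.
#' @export
read_codon_alignment <- function(path, gene_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(gene_id))
    gene_id <- sub("\\.[^.]*$", "", basename(path))
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in: ", paste(names(seqs)[bad], collapse = ", "))
  if (any(nchar(seqs) %% 3L != 0L))
    stop("codon alignment length must be divisible by 3")
  aa <- vapply(seqs, translate_cds, character(1), allow_missing = TRUE)
  ortholog_gene(gene_id, aa, codons = seqs)
}

# Translate a CDS, mapping codons containing '-'/'N' to 'X' and stops to 'X'
# when allow_missing (alignment context); otherwise internal stops raise.
translate_cds <- function(cds, allow_missing = FALSE) {
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  code <- GENETIC_CODE_TABLE()
  aa <- ifelse(grepl("[-N]", codons), "X", unname(code[codons]))
  aa[is.na(aa)] <- "X"
  if (any(aa == "*")) {
    if (!allow_missing) stop("internal stop codon in CDS")
    aa[aa == "*"] <- "X"
  }
  paste(aa, collapse = "")
}

GENETIC_CODE_TABLE <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
}

#' Read a species-role configuration
#'
#' The file is a tab-separated table with columns `species`, `role`,
#' `clade` and optionally `closest_relative` (use `.` or empty for none).
#' Roles are `focal_key`, `focal_extra`, `control_key`, `control_extra`
#' and `outgroup`.  The configuration encodes the symmetric design: each
#' focal key species is paired with exactly one control key species
#' carrying the same clade label, and a single outgroup anchors the
#' ancestral state.
#'
#' @param path TSV file.
#' @return a validated `species_roles` data frame.
#' @export
read_role_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("species", "role", "clade") %in% names(df)))
    stop("role config needs columns species, role, clade")
  if (is.null(df$closest_relative)) df$closest_relative <- NA_character_
  df$closest_relative[df$closest_relative %in% c("", ".")] <- NA_character_
  species_roles(df)
}

#' Construct and validate a species-role configuration
#'
#' @param df data frame with columns `species`, `role`, `clade`,
#'   optionally `closest_relative`.
#' @return object of class `species_roles` (a data frame).
#' @export
species_roles <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$closest_relative)) df$closest_relative <- NA_character_
  df <- df[, c("species", "role", "clade", "closest_relative")]
  if (anyDuplicated(df$species))
    stop("duplicate species id in role config: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  bad_role <- setdiff(unique(df$role), ROLE_LEVELS)
  if (length(bad_role))
    stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  if (sum(df$role == "outgroup") != 1L)
    stop("role config must contain exactly one outgroup")
  fk <- df[df$role == "focal_key", ]
  ck <- df[df$role == "control_key", ]
  if (nrow(fk) < 2L)
    stop("need at least two focal_key species")
  for (cl in fk$clade) {
    if (sum(ck$clade == cl) != 1L)
      stop(sprintf(
        "focal_key clade '%s' must be paired with exactly one control_key", cl))
  }
  if (nrow(ck) != nrow(fk))
    stop("every control_key must pair a focal_key (counts differ)")
  rel <- df$closest_relative[!is.na(df$closest_relative)]
  dangling <- setdiff(rel, df$species)
  if (length(dangling))
    stop("closest_relative id(s) not in config: ",
         paste(dangling, collapse = ", "))
  rownames(df) <- NULL
  structure(df, class = c("species_roles", "data.frame"))
}

#' Species ids holding a given role
#' @param roles a `species_roles` object.
#' @param role one of the role levels.
#' @return character vector of species ids (possibly empty).
#' @export
role_species <- function(roles, role) {
  role <- match.arg(role, ROLE_LEVELS)
  roles$species[roles$role == role]
}

#' Swap focal and control roles
#'
#' Exchanges `focal_key` with `control_key` and `focal_extra` with
#' `control_extra`; used to run the empirical control direction with the
#' identical machinery.
#'
#' @param roles a `species_roles` object.
#' @return a `species_roles` object with roles swapped.
#' @export
swap_roles <- function(roles) {
  map <- c(focal_key = "control_key", control_key = "focal_key",
           focal_extra = "control_extra", control_extra = "focal_extra",
           outgroup = "outgroup")
  roles$role <- unname(map[roles$role])
  species_roles(roles)
}

#' Read a rooted phylogeny with branch lengths
#'
#' Thin wrapper over [ape::read.tree()] that enforces what the simulator
#' needs: unique tips, branch lengths present on every edge, none negative.
#'
#' @param path Newick file.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("unparseable Newick in ", path)
  validate_tree(tr)
}

#' @rdname read_tree
#' @param tree an [ape::phylo] object to validate in memory.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge)
      || anyNA(tree$edge.length))
    stop("tree must have a branch length on every edge")
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) in tree")
  tree
}

#' Read a two-column annotation table
#'
#' @param path TSV with header columns `gene_id` and a single label column
#'   (any name, e.g. `location` or `pathway`).
#' @return data frame with unique `gene_id`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L || names(df)[1L] != "gene_id")
    stop("annotation table needs a gene_id column followed by a label column")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in annotation table")
  df
}

#' Write site calls as a TSV report
#'
#' Columns are 1-based in reports (stated in the header line).
#'
#' @param calls site-call data frame from [call_site_convergence()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_site_calls <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# site calls; 'column' is 1-based", con)
  out <- calls
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a site-call TSV
#' @param path file written by [write_site_calls()].
#' @return data frame of calls.
#' @export
read_site_calls <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
}

#' Write a summary object as JSON
#' @param x a list-like summary (e.g. from [summarize_step1()]).
#' @param path output JSON file.
#' @return invisibly, the path.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  lines <- character(2L * length(seqs))
  lines[seq(1L, by = 2L, length.out = length(seqs))] <- paste0(">", names(seqs))
  lines[seq(2L, by = 2L, length.out = length(seqs))] <- unname(seqs)
  writeLines(lines, path)
  invisible(path)
}
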