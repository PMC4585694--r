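# Real-value Evolutionary-Trace-style conservation: alignment columns
# are ranked by summing Shannon entropies of sub-alignments defined by
# cutting a phylogenetic tree at successively lower internal nodes; a
# residue fixed early along the tree (low rank) is conserved.

#' Construct an MSA object
#'
#' @param ids character vector of record identifiers.
#' @param seqs character vector of aligned sequences (equal length,
#'   alphabet: the 20 amino acids plus `-`; `.` and `~` are read as
#'   gaps, any other symbol is converted to a gap with a warning).
#' @param reference_id id of the reference sequence whose positions
#'   index the conservation profile.
#' @return an object of class `MSA`.
#' @export
msa <- function(ids, seqs, reference_id = ids[1]) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (anyDuplicated(ids)) stop("duplicated record ids")
  if (length(unique(nchar(seqs))) != 1)
    stop("aligned sequences must all have the same length")
  if (!reference_id %in% ids)
    stop("reference id '", reference_id, "' not in alignment")
  seqs <- gsub("[.~]", "-", seqs)
  other <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                   c(AA20, "-"))
  if (length(other)) {
    warning("non-standard symbol(s) ", paste(other, collapse = ""),
            " converted to gaps")
    seqs <- chartr(paste(other, collapse = ""),
                   strrep("-", length(other)), seqs)
  }
  structure(list(ids = ids, seqs = setNames(seqs, ids),
                 reference_id = reference_id,
                 n_columns = nchar(seqs[1])),
            class = "MSA")
}

#' @export
print.MSA <- function(x, ...) {
  cat("MSA: ", length(x$ids), " sequences x ", x$n_columns,
      " columns (reference: ", x$reference_id, ")\n", sep = "")
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' @param path alignment file path.
#' @param format `"fasta"` or `"clustal"`.
#' @param reference_id reference record id; defaults to the first
#'   record.
#' @return an `MSA`.
#' @export
read_msa <- function(path, format = c("fasta", "clustal"),
                     reference_id = NULL) {
  format <- match.arg(format)
  aln <- seqinr::read.alignment(path, format = format)
  if (is.null(aln$nb) || aln$nb < 1) stop("no sequences in '", path, "'")
  ids <- sub("\\s.*$", "", aln$nam)
  if (is.null(reference_id)) reference_id <- ids[1]
  msa(ids, unlist(aln$seq), reference_id)
}

#' Write an MSA as aligned FASTA
#' @param x an `MSA`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(x, path) {
  seqinr::write.fasta(as.list(unname(x$seqs)), names = x$ids,
                      file.out = path, nbchar = 60)
  invisible(path)
}

#' Homolog-set filtering against a reference sequence
#'
#' Drops candidate sequences identical to the reference and sequences
#' whose ungapped length is below `min_len_frac` times the reference
#' length; the reference itself is retained once at the head of the
#' returned set.
#'
#' @param raw named character vector of candidate sequences (gaps
#'   allowed; compared ungapped).
#' @param reference the reference sequence (ungapped).
#' @param min_len_frac minimum length fraction (default 0.8).
#' @param reference_id name given to the retained reference record.
#' @return named character vector: reference first, then survivors.
#' @export
filter_sequences <- function(raw, reference, min_len_frac = 0.8,
                             reference_id = "reference") {
  stopifnot(nchar(reference) > 0, min_len_frac > 0, min_len_frac <= 1)
  if (is.null(names(raw))) names(raw) <- paste0("seq", seq_along(raw))
  refu <- toupper(gsub("-", "", reference))
  ung <- toupper(gsub("-", "", raw))
  keep <- ung != refu & nchar(ung) >= min_len_frac * nchar(refu)
  if (!any(keep))
    stop("no candidate sequences survive the length/identity filters")
  out <- c(setNames(refu, reference_id), ung[keep])
  out
}

# p-distance: fraction of mismatched columns among columns where both
# sequences are ungapped; 1 when no comparable column exists.
p_distance_matrix <- function(x) {
  m <- do.call(rbind, strsplit(unname(x$seqs), ""))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(x$ids, x$ids))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      ok <- m[a, ] != "-" & m[b, ] != "-"
      d[a, b] <- d[b, a] <-
        if (!any(ok)) 1 else mean(m[a, ok] != m[b, ok])
    }
  }
  d
}

#' Build a rooted phylogenetic tree from an MSA
#'
#' Neighbor-joining on p-distances (fraction of mismatched non-gap
#' columns), midpoint-rooted; negative NJ branch lengths are clamped to
#' zero. Deterministic given the alignment. An externally built tree
#' can be supplied to [rvet_scores()] instead.
#'
#' @param x an `MSA` with at least two records.
#' @return a rooted binary `phylo` tree whose tips are the MSA ids.
#' @export
build_tree <- function(x) {
  stopifnot(inherits(x, "MSA"))
  n <- length(x$ids)
  if (n < 2) stop("need at least 2 sequences to build a tree")
  d <- p_distance_matrix(x)
  if (n == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                        x$ids[1], d[1, 2] / 2,
                                        x$ids[2], d[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- phangorn::midpoint(tr)
  if (!ape::is.binary(tr)) tr <- ape::multi2di(tr, random = FALSE)
  tr
}

# Internal nodes ordered root-first by increasing depth from the root
# (equivalently decreasing height), ties broken by preorder index.
ordered_internal_nodes <- function(tr) {
  tr <- ape::reorder.phylo(tr, "cladewise")
  ntip <- length(tr$tip.label)
  depth <- ape::node.depth.edgelength(tr)
  internal <- (ntip + 1):(ntip + tr$Nnode)
  pre <- match(internal, unique(tr$edge[, 1]))
  list(tree = tr, nodes = internal[order(depth[internal], pre)])
}

#' Leaf partitions from successive tree cuts
#'
#' For `n = 1 .. N-1` (N leaves), partition `n` is obtained by cutting
#' the tree at its `n - 1` highest internal nodes (root first,
#' descending height, ties by deterministic preorder index): level 1
#' puts all leaves in one group and the partitions are nested.
#'
#' @param tr a rooted binary `phylo` tree.
#' @return list of length `N - 1`; element `n` is a list of `n`
#'   character vectors of tip labels.
#' @export
level_partitions <- function(tr) {
  stopifnot(inherits(tr, "phylo"))
  oi <- ordered_internal_nodes(tr)
  tr <- oi$tree
  ntip <- length(tr$tip.label)
  if (ntip < 2) stop("tree must have at least 2 leaves")
  tips_under <- function(node) {
    if (node <= ntip) return(tr$tip.label[node])
    tr$tip.label[phangorn::Descendants(tr, node, "tips")[[1]]]
  }
  out <- vector("list", ntip - 1)
  out[[1]] <- list(sort(tr$tip.label))
  if (ntip == 2) return(out)
  for (n in 2:(ntip - 1)) {
    cut_set <- oi$nodes[seq_len(n - 1)]
    frontier <- tr$edge[tr$edge[, 1] %in% cut_set &
                        !tr$edge[, 2] %in% cut_set, 2]
    out[[n]] <- lapply(sort(frontier), function(nd) sort(tips_under(nd)))
  }
  out
}

# Shannon entropy (natural log) of each alignment column within a leaf
# group; gaps are excluded from the frequencies and an all-gap column
# contributes zero.
group_column_entropies <- function(char_mat, rows) {
  sub <- char_mat[rows, , drop = FALSE]
  apply(sub, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return(0)
    p <- tabulate(factor(col, levels = AA20), nbins = 20)
    p <- p[p > 0] / length(col)
    -sum(p * log(p))
  })
}

#' Real-value Evolutionary-Trace-style conservation scores
#'
#' For each alignment column `i` the score is
#' `rho_i = 1 + sum_{n=1}^{N-1} (1/n) sum_g H_g(i)`, where at level `n`
#' the `N` leaves are split into `n` groups by cutting the tree at its
#' `n - 1` highest internal nodes and `H_g(i)` is the Shannon entropy
#' (natural log) of the amino-acid frequencies of column `i` within
#' group `g` (gaps excluded; an all-gap group contributes 0). An
#' invariant column scores exactly 1; lower is more conserved. Columns
#' where the reference is gapped are absent from the profile.
#'
#' @param x an `MSA`.
#' @param tree optional rooted `phylo` tree over the MSA ids; built
#'   with [build_tree()] when omitted.
#' @param cutoff conservation cutoff: a position is conserved (`C`)
#'   when `rho < cutoff`, non-conserved (`NC`) otherwise (default 5).
#' @return a `ConservationProfile`: data.frame with columns `position`
#'   (reference numbering), `aa`, `column` (MSA column), `rvet`,
#'   `state`.
#' @export
rvet_scores <- function(x, tree = NULL, cutoff = 5) {
  stopifnot(inherits(x, "MSA"))
  if (is.null(tree)) tree <- build_tree(x)
  if (!setequal(tree$tip.label, x$ids))
    stop("tree leaf set does not match the MSA record ids")
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)

  char_mat <- do.call(rbind, strsplit(unname(x$seqs), ""))
  rownames(char_mat) <- x$ids
  ntip <- length(x$ids)
  parts <- level_partitions(tree)

  ent_cache <- new.env(parent = emptyenv())
  group_ent <- function(members) {
    key <- paste(members, collapse = "\r")
    if (is.null(ent_cache[[key]]))
      ent_cache[[key]] <- group_column_entropies(char_mat, members)
    ent_cache[[key]]
  }
  rho <- rep(1, x$n_columns)
  for (n in seq_along(parts)) {
    lvl <- numeric(x$n_columns)
    for (g in parts[[n]]) lvl <- lvl + group_ent(g)
    rho <- rho + lvl / n
  }

  ref <- char_mat[x$reference_id, ]
  keep <- which(ref != "-")
  out <- data.frame(position = seq_along(keep),
                    aa = ref[keep],
                    column = keep,
                    rvet = rho[keep],
                    state = conservation_state(rho[keep], cutoff),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ConservationProfile", "data.frame")
  attr(out, "cutoff") <- cutoff
  out
}

#' Choose a conservation cutoff from the score distribution
#'
#' Splits the observed rvET scores into two groups by 2-means
#' clustering and places the cutoff at the midpoint of the empirical
#' gap between the groups (halfway between the largest low-group score
#' and the smallest high-group score), mirroring a cutoff choice based
#' on the score distribution rather than a fixed constant. Falls back
#' to the fixed default when the scores do not separate.
#'
#' @param rho numeric vector of rvET scores.
#' @param default cutoff returned when all scores are (nearly) equal.
#' @return numeric cutoff.
#' @export
conservation_cutoff_from_distribution <- function(rho, default = 5) {
  if (length(unique(round(rho, 10))) < 2) return(default)
  km <- kmeans(rho, centers = 2, nstart = 5)
  lo <- which.min(km$centers)
  (max(rho[km$cluster == lo]) + min(rho[km$cluster != lo])) / 2
}

#' Conservation state from an rvET score
#'
#' Conserved (`C`) strictly below the cutoff, non-conserved (`NC`)
#' otherwise; a score exactly at the cutoff is non-conserved.
#'
#' @param rho numeric vector of rvET scores.
#' @param cutoff conservation cutoff (default 5).
#' @return character vector in `{C, NC}`.
#' @export
conservation_state <- function(rho, cutoff = 5) {
  ifelse(rho < cutoff, "C", "NC")
}
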