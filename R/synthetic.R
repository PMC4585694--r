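# Ground-truth-labelled synthetic data: deterministic helical-arc
# structures whose sequences can be designed to be minimally or highly
# frustrated at chosen positions, two-chain complexes contacting a
# prescribed interface, and alignments evolved down a known tree with
# per-column rate classes. Geometry is a fixed template curve, not a
# physical simulation: the frustration machinery only needs a contact
# graph.

# Helix template: CA on a cylinder (radius 2.3 A, rise 1.45 A, 100 deg
# per residue), CB displaced 1.5 A radially outward. At the default
# 6.5 A site cutoff this yields i+/-3 and i+/-4 contacts, so interior
# residues have four contacts each.
helix_coords <- function(n, r_ca = 2.3, r_cb = 3.8, rise = 1.45,
                         twist_deg = 100) {
  k <- seq_len(n) - 1
  th <- k * twist_deg * pi / 180
  list(ca = cbind(x = r_ca * cos(th), y = r_ca * sin(th), z = rise * k),
       cb = cbind(x = r_cb * cos(th), y = r_cb * sin(th), z = rise * k),
       theta = th, zed = rise * k)
}

#' Generate a synthetic single-chain structure
#'
#' Deterministic helical-arc backbone with a seed-determined random
#' sequence: the same seed reproduces coordinates and sequence
#' bit-identically, a different seed changes the sequence but not the
#' backbone template. Residue sites are the CB positions (CA for
#' glycine). The structure round-trips through [write_structure()] /
#' [load_structure()].
#'
#' @param n chain length (>= 5).
#' @param seed integer seed for the sequence draw.
#' @param chain_id chain identifier.
#' @param sequence optional explicit one-letter sequence overriding the
#'   random draw.
#' @return a `StructureModel`.
#' @export
make_structure <- function(n, seed = 1L, chain_id = "A", sequence = NULL) {
  if (n < 5) stop("synthetic chain length must be at least 5")
  if (is.null(sequence)) {
    sequence <- with_rng_seed(seed,
      paste(sample(AA20, n, replace = TRUE), collapse = ""))
  }
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) != n) stop("sequence length does not match n")
  geo <- helix_coords(n)
  site <- geo$cb
  site[aa == "G", ] <- geo$ca[aa == "G", ]
  structure_model(
    data.frame(chain = chain_id, resno = seq_len(n), aa = aa,
               x = site[, "x"], y = site[, "y"], z = site[, "z"],
               stringsAsFactors = FALSE),
    id = sprintf("synthetic_%s_n%d_seed%d", chain_id, n, seed))
}

#' Design a sequence with prescribed frustration at chosen positions
#'
#' Iteratively (fixed sweep order, at most `max_sweeps` sweeps)
#' assigns, at each MF-designed position, the identity minimizing the
#' residue's native contact energy given its current neighbours, and at
#' each HF-designed position the maximizing identity; all other
#' positions keep their current identities. On return every designed
#' position is locally optimal (no single-identity change improves it
#' in the designed direction) unless `converged` is `FALSE`.
#'
#' @param s a StructureModel.
#' @param designed named character vector: names are author residue
#'   numbers (in `chain`), values `"MF"` or `"HF"`.
#' @param em an EnergyModel (its contact rule is used).
#' @param chain chain holding the designed positions.
#' @param max_sweeps sweep limit (default 10).
#' @return list with `structure` (redesigned model), `converged`,
#'   `sweeps`.
#' @export
design_sequence <- function(s, designed, em, chain = chain_ids(s)[1],
                            max_sweeps = 10L) {
  stopifnot(inherits(s, "StructureModel"), length(designed) >= 1)
  if (!all(designed %in% c("MF", "HF")))
    stop("designed values must be 'MF' or 'HF'")
  pos <- as.integer(names(designed))
  idx <- match(paste(chain, pos), paste(s$residues$chain, s$residues$resno))
  if (anyNA(idx)) stop("designed position(s) absent from chain ", chain)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    cm <- contact_map(s, em$contact_cutoff_A, em$min_seq_sep)
    nb <- contact_neighbors(cm, n_residues(s))
    changed <- FALSE
    for (k in seq_along(idx)) {
      v <- candidate_energy_vector(s, nb[[idx[k]]], em)
      pick <- if (designed[k] == "MF") AA20[which.min(v)] else
        AA20[which.max(v)]
      if (s$residues$aa[idx[k]] != pick) {
        s$residues$aa[idx[k]] <- pick
        changed <- TRUE
      }
    }
    if (!changed || sweeps >= max_sweeps) break
  }
  # verify local optimality under the final contact map
  cm <- contact_map(s, em$contact_cutoff_A, em$min_seq_sep)
  nb <- contact_neighbors(cm, n_residues(s))
  ok <- vapply(seq_along(idx), function(k) {
    v <- candidate_energy_vector(s, nb[[idx[k]]], em)
    vi <- v[s$residues$aa[idx[k]]]
    if (designed[k] == "MF") vi <= min(v) + 1e-12 else vi >= max(v) - 1e-12
  }, TRUE)
  list(structure = s, converged = all(ok) && !changed, sweeps = sweeps)
}

#' Generate a two-chain complex with a prescribed interface
#'
#' Places a target chain so that target residue `k` contacts exactly
#' receptor residue `interface_positions[k]` (each target site 6.0 A
#' radially outward of its receptor partner's site) and verifies
#' against [contact_map()] that the inter-chain contact set equals the
#' designed interface, erroring otherwise.
#'
#' @param receptor a single-chain StructureModel (helical-arc
#'   geometry from [make_structure()]).
#' @param interface_positions receptor author residue numbers contacted
#'   by the target (one target residue each). May be empty for a
#'   contact-free target.
#' @param seed seed for the target-sequence draw.
#' @param target_seq optional explicit target sequence.
#' @param target_chain target chain id.
#' @return a two-chain `StructureModel`.
#' @export
make_complex <- function(receptor, interface_positions, seed = 1L,
                         target_seq = NULL, target_chain = "B") {
  stopifnot(inherits(receptor, "StructureModel"))
  if (length(chain_ids(receptor)) != 1)
    stop("receptor must be single-chain")
  rch <- chain_ids(receptor)
  m <- length(interface_positions)
  if (anyDuplicated(interface_positions))
    stop("interface positions must be unique")
  n_t <- max(m, 3L)  # a target chain needs a few residues even with no interface
  if (is.null(target_seq)) {
    target_seq <- with_rng_seed(seed + 1L,
      paste(sample(AA20, n_t, replace = TRUE), collapse = ""))
  }
  taa <- strsplit(target_seq, "")[[1]]
  if (length(taa) < m) stop("target sequence shorter than the interface")
  n_t <- length(taa)

  res <- receptor$residues
  tx <- ty <- tz <- numeric(n_t)
  if (m > 0) {
    ridx <- match(interface_positions, res$resno)
    if (anyNA(ridx)) stop("interface position(s) absent from receptor")
    for (k in seq_len(m)) {
      p <- c(res$x[ridx[k]], res$y[ridx[k]], res$z[ridx[k]])
      u <- c(p[1], p[2], 0)
      nu <- sqrt(sum(u^2))
      if (nu < 1e-9) u <- c(1, 0, 0) else u <- u / nu
      q <- p + 6.0 * u
      tx[k] <- q[1]; ty[k] <- q[2]; tz[k] <- q[3]
    }
    extra <- seq_len(n_t)[-seq_len(m)]
  } else {
    extra <- seq_len(n_t)
  }
  # remaining target residues parked far from the receptor
  far_z <- max(res$z) + 60
  for (j in seq_along(extra)) {
    tx[extra[j]] <- 0; ty[extra[j]] <- 0; tz[extra[j]] <- far_z + 8 * j
  }
  cplx <- structure_model(
    rbind(res,
          data.frame(chain = target_chain, resno = seq_len(n_t), aa = taa,
                     x = tx, y = ty, z = tz, stringsAsFactors = FALSE)),
    id = paste0(receptor$id, "_complex_seed", seed))

  cm <- contact_map(cplx, 6.5, 2L)
  rr <- cplx$residues
  inter <- cm$pairs[rr$chain[cm$pairs$i] != rr$chain[cm$pairs$j], ,
                    drop = FALSE]
  got <- sort(paste(rr$resno[inter$i], rr$resno[inter$j]))
  want <- if (m > 0) sort(paste(interface_positions, seq_len(m))) else
    character(0)
  if (!identical(got, want))
    stop("target placement failed: inter-chain contacts ",
         paste(got, collapse = "; "), " != designed ",
         paste(want, collapse = "; "))
  cplx
}

#' Simulate an alignment down a known tree with per-column rate classes
#'
#' A root sequence evolves along a (supplied or simulated coalescent)
#' tree under uniform replacement: on a branch of length `b`, a column
#' of rate `r` is replaced, with probability `1 - exp(-r * b)`, by an
#' identity drawn uniformly from the 20 amino acids (so two leaves
#' whose path to the common ancestor has replacement probabilities
#' `a1`, `a2` mismatch with probability `(19/20) * (1 - (1-a1)(1-a2))`).
#' Invariant columns never change. No indels are introduced.
#'
#' @param n_leaves number of leaves when `tree` is not supplied.
#' @param rate_classes character vector over columns, each `"invariant"`,
#'   `"slow"` or `"fast"`.
#' @param rates named replacement rates per class (substitutions per
#'   unit branch length).
#' @param tree optional rooted `phylo`; when omitted a coalescent tree
#'   is simulated and rescaled to depth 1.
#' @param root_seq optional root sequence (length = number of columns).
#' @param seed integer seed.
#' @param include_root when `TRUE`, the (unevolved) root sequence is
#'   added to the alignment as record `"ref"`, attached to the tree as
#'   a zero-length tip at the root, and used as the reference — this
#'   mirrors an analysis where the structure's own sequence sits in the
#'   homolog set.
#' @return list with `msa`, `tree` (leaf set = MSA ids), `labels` (the
#'   rate classes), `root_seq`.
#' @export
simulate_msa <- function(n_leaves = 32L, rate_classes,
                         rates = c(invariant = 0, slow = 0.3, fast = 3),
                         tree = NULL, root_seq = NULL, seed = 1L,
                         include_root = FALSE) {
  stopifnot(all(rate_classes %in% names(rates)))
  L <- length(rate_classes)
  with_rng_seed(seed, {
    if (is.null(tree)) {
      tree <- ape::rcoal(n_leaves, tip.label = paste0("t", seq_len(n_leaves)))
      depth <- max(ape::node.depth.edgelength(tree))
      tree$edge.length <- tree$edge.length / depth
    }
    ntip <- length(tree$tip.label)
    if (is.null(root_seq))
      root_seq <- paste(sample(AA20, L, replace = TRUE), collapse = "")
    root <- strsplit(root_seq, "")[[1]]
    if (length(root) != L) stop("root sequence length must match columns")
    rate_col <- unname(rates[rate_classes])

    seqs <- matrix(NA_character_, ntip + tree$Nnode, L)
    seqs[ntip + 1, ] <- root
    tr <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      b <- tr$edge.length[e]
      sq <- seqs[par, ]
      p_sub <- 1 - exp(-rate_col * b)
      hit <- stats::runif(L) < p_sub
      if (any(hit)) sq[hit] <- sample(AA20, sum(hit), replace = TRUE)
      seqs[child, ] <- sq
    }
    leaves <- apply(seqs[seq_len(ntip), , drop = FALSE], 1, paste,
                    collapse = "")
    ids <- tree$tip.label
    if (include_root) {
      ids <- c("ref", ids)
      leaves <- c(root_seq, leaves)
      nwk <- sub(";\\s*$", "", ape::write.tree(tree))
      tree <- ape::read.tree(text = sprintf("(ref:0,%s:0);", nwk))
    }
    list(msa = msa(ids, leaves,
                   reference_id = if (include_root) "ref" else ids[1]),
         tree = tree, labels = rate_classes, root_seq = root_seq)
  })
}

#' Rank-based AUC of a score separating two groups
#'
#' Probability, under the Mann-Whitney statistic, that a score drawn
#' from `high` exceeds one drawn from `low` (ties count one half).
#'
#' @param high scores of the group expected to score higher.
#' @param low scores of the group expected to score lower.
#' @return AUC in `[0, 1]`.
#' @export
ranking_auc <- function(high, low) {
  n1 <- length(high); n2 <- length(low)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(high, low))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
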