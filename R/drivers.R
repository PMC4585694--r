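# Pipeline drivers: thin, file-in/file-out wrappers over the analysis
# modules, shared by scripted use and the command-line entry point
# (inst/cli/frustrace.R). All outputs are TSV; nothing mutates its
# inputs; logging goes to stderr via message().

#' Default run configuration
#'
#' Cutoffs mirror the analysis defaults: SRLF classification at +/-1,
#' conservation at rvET 5, contacts at 6.5 angstroms with within-chain
#' separation >= 2, composition-weighted decoys, 2000 decoys per
#' residue.
#'
#' @param ... overrides of the defaults, by name.
#' @return named list of configuration values.
#' @export
frustrace_config <- function(...) {
  cfg <- list(matrix_path = "",
              contact_cutoff_A = 6.5,
              min_seq_sep = 2,
              decoy_policy = "composition",
              n_decoys = 2000,
              seed = 1,
              srlf_cutoff = 1,
              rvet_cutoff = 5,
              min_identity = 0.6)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (one per line, `#` comments);
#' numeric-looking values are coerced. Unset keys keep their defaults.
#'
#' @param path configuration file path.
#' @return configuration list as from [frustrace_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(p) {
    v <- p[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, "", 1)
  do.call(frustrace_config, vals)
}

config_energy_model <- function(cfg) {
  mp <- if (is.null(cfg$matrix_path) || !nzchar(cfg$matrix_path)) NULL else
    cfg$matrix_path
  default_energy_model(matrix_path = mp,
                       contact_cutoff_A = cfg$contact_cutoff_A,
                       min_seq_sep = cfg$min_seq_sep,
                       decoy_policy = cfg$decoy_policy,
                       n_decoys = cfg$n_decoys,
                       seed = cfg$seed)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Frustration pipeline over structure files
#'
#' For every readable structure file, writes the bound frustration
#' profile `<id>_bound.tsv` and, when a receptor chain is given, the
#' unbound (target-removed) profile and the bound-vs-unbound delta
#' table. Unreadable files are skipped with a warning; the run errors
#' only when every file fails.
#'
#' @param paths PDB file paths.
#' @param out_dir output directory (created if missing).
#' @param config configuration list from [frustrace_config()].
#' @param receptor_chains optional receptor chain id per file
#'   (recycled).
#' @return invisibly, the written file paths.
#' @export
run_frustration <- function(paths, out_dir, config = frustrace_config(),
                            receptor_chains = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  em <- config_energy_model(config)
  if (!is.null(receptor_chains))
    receptor_chains <- rep_len(receptor_chains, length(paths))
  written <- character(0)
  n_ok <- 0L
  for (k in seq_along(paths)) {
    s <- tryCatch(load_structure(paths[k]), error = function(e) {
      warning("skipping '", paths[k], "': ", conditionMessage(e))
      NULL
    })
    if (is.null(s)) next
    n_ok <- n_ok + 1L
    message("frustration: ", s$id, " (", n_residues(s), " residues, seed ",
            em$seed, ")")
    bound <- frustration_profile(s, em)
    if (any(bound$degenerate))
      message("  note: ", sum(bound$degenerate),
              " degenerate residue(s) (zero decoy spread)")
    f <- file.path(out_dir, paste0(s$id, "_bound.tsv"))
    write_tsv(bound, f)
    written <- c(written, f)
    if (!is.null(receptor_chains)) {
      unb <- unbound_profile(s, receptor_chains[k], em)
      f2 <- file.path(out_dir, paste0(s$id, "_unbound.tsv"))
      write_tsv(unb, f2)
      f3 <- file.path(out_dir, paste0(s$id, "_delta.tsv"))
      write_tsv(delta_frustration(bound, unb), f3)
      written <- c(written, f2, f3)
    }
  }
  if (n_ok == 0) stop("no structure file could be processed")
  invisible(written)
}

#' Conservation pipeline over an alignment
#'
#' Reads the alignment (FASTA by default; `.aln`/`.clustal` files as
#' Clustal), builds the neighbor-joining tree unless one is supplied as
#' Newick, and writes the rvET conservation profile (and the built
#' tree).
#'
#' @param msa_path alignment file.
#' @param out_dir output directory.
#' @param tree_path optional Newick tree over the alignment ids.
#' @param config configuration list.
#' @param reference_id reference record id (default first record).
#' @return invisibly, the written file paths.
#' @export
run_conservation <- function(msa_path, out_dir, tree_path = NULL,
                             config = frustrace_config(),
                             reference_id = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- if (grepl("\\.(aln|clustal)$", msa_path, ignore.case = TRUE))
    "clustal" else "fasta"
  x <- read_msa(msa_path, format = fmt, reference_id = reference_id)
  written <- character(0)
  if (is.null(tree_path)) {
    tree <- build_tree(x)
    tf <- file.path(out_dir, "tree.nwk")
    ape::write.tree(tree, tf)
    written <- c(written, tf)
  } else {
    tree <- ape::read.tree(tree_path)
  }
  prof <- rvet_scores(x, tree = tree, cutoff = config$rvet_cutoff)
  message("conservation: ", length(x$ids), " sequences, ",
          nrow(prof), " reference positions, cutoff ", config$rvet_cutoff)
  f <- file.path(out_dir, "conservation.tsv")
  write_tsv(prof, f)
  invisible(c(written, f))
}

#' Read a frustration-profile TSV back into a FrustrationProfile
#' @param path TSV written by [run_frustration()].
#' @return a `FrustrationProfile`.
#' @export
read_profile_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("FrustrationProfile", "data.frame")
  df
}

#' Read a conservation-profile TSV back into a ConservationProfile
#' @param path TSV written by [run_conservation()].
#' @param cutoff the conservation cutoff recorded with the profile.
#' @return a `ConservationProfile`.
#' @export
read_conservation_tsv <- function(path, cutoff = 5) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("ConservationProfile", "data.frame")
  attr(df, "cutoff") <- cutoff
  df
}

#' Classification pipeline joining frustration and conservation
#'
#' Reads bound-profile TSVs and a conservation TSV, aggregates them
#' into the six-class ensemble table, and writes the per-residue table,
#' the per-complex class-fraction table and the 2D histogram table.
#'
#' @param profile_paths bound frustration-profile TSVs (one per
#'   complex).
#' @param conservation_path conservation TSV.
#' @param out_dir output directory.
#' @param config configuration list.
#' @param receptor_chains receptor chain per profile (default: first
#'   chain of each).
#' @return invisibly, the `ResidueClassTable`.
#' @export
run_classify <- function(profile_paths, conservation_path, out_dir,
                         config = frustrace_config(),
                         receptor_chains = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- lapply(profile_paths, read_profile_tsv)
  names(profiles) <- sub("_bound\\.tsv$", "", basename(profile_paths))
  cons <- read_conservation_tsv(conservation_path,
                                cutoff = config$rvet_cutoff)
  tab <- aggregate_classes(profiles, cons,
                           receptor_chains = receptor_chains,
                           min_identity = config$min_identity)
  message("classify: ", nrow(tab$by_residue), " reference positions x ",
          length(profiles), " complex(es)")
  write_tsv(tab$by_residue, file.path(out_dir, "residue_classes.tsv"))
  write_tsv(tab$class_fractions, file.path(out_dir, "class_fractions.tsv"))
  tdm <- two_d_map(tab)
  write_tsv(tdm$histogram, file.path(out_dir, "class_histogram.tsv"))
  write_tsv(tdm$points, file.path(out_dir, "map_points.tsv"))
  if (nrow(tab$unmapped))
    write_tsv(tab$unmapped, file.path(out_dir, "unmapped_residues.tsv"))
  invisible(tab)
}

#' Generate a labelled synthetic benchmark dataset
#'
#' Writes a designed receptor, an ensemble of two-chain complexes, a
#' simulated alignment with its tree, and ground-truth label TSVs, all
#' derived deterministically from one seed.
#'
#' @param out_dir output directory.
#' @param n_res receptor length.
#' @param n_complexes number of complexes.
#' @param n_leaves leaves of the simulated tree.
#' @param mf_positions,hf_positions designed MF/HF receptor positions.
#' @param invariant_frac fraction of invariant alignment columns.
#' @param seed integer seed.
#' @param config configuration list.
#' @return invisibly, a list with the generated objects and the label
#'   tables.
#' @export
run_simulate <- function(out_dir, n_res = 60L, n_complexes = 10L,
                         n_leaves = 32L,
                         mf_positions = NULL, hf_positions = NULL,
                         invariant_frac = 0.3, seed = 1L,
                         config = frustrace_config(seed = seed)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  em <- config_energy_model(config)
  bench <- synthetic_benchmark(n_res = n_res, n_complexes = n_complexes,
                               n_leaves = n_leaves,
                               mf_positions = mf_positions,
                               hf_positions = hf_positions,
                               invariant_frac = invariant_frac,
                               seed = seed, em = em)
  write_structure(bench$receptor, file.path(out_dir, "receptor.pdb"))
  for (k in seq_along(bench$complexes))
    write_structure(bench$complexes[[k]],
                    file.path(out_dir, sprintf("complex_%02d.pdb", k)))
  write_msa(bench$sim$msa, file.path(out_dir, "msa.fasta"))
  ape::write.tree(bench$sim$tree, file.path(out_dir, "tree.nwk"))
  write_tsv(bench$labels, file.path(out_dir, "labels.tsv"))
  message("simulate: receptor n=", n_res, ", ", n_complexes,
          " complexes, ", n_leaves, "-leaf alignment, seed ", seed)
  invisible(bench)
}

#' Assemble the standard synthetic benchmark
#'
#' One designed receptor (chosen positions minimally or highly
#' frustrated), an ensemble of complexes binding it at varying
#' interfaces, and an alignment simulated down a known tree whose
#' column rate classes (invariant vs fast) carry the conservation
#' ground truth. Designed positions are matched one-to-one with
#' alignment columns (residue k of the receptor is column k), so each
#' designed residue has a known six-class label.
#'
#' @inheritParams run_simulate
#' @param em an EnergyModel.
#' @return list with `receptor`, `complexes`, `sim` (see
#'   [simulate_msa()]) and `labels` (per designed position: designed
#'   frustration, conservation and six-class label).
#' @export
synthetic_benchmark <- function(n_res = 60L, n_complexes = 10L,
                                n_leaves = 32L, mf_positions = NULL,
                                hf_positions = NULL, invariant_frac = 0.3,
                                seed = 1L, em = default_energy_model(seed = seed)) {
  # designed positions are spaced beyond the helix contact shell
  # (i +/- 3, i +/- 4) so their designs do not couple to each other
  if (is.null(mf_positions))
    mf_positions <- seq(6L, n_res - 14L, by = 10L)
  if (is.null(hf_positions))
    hf_positions <- mf_positions + 5L
  if (length(intersect(mf_positions, hf_positions)))
    stop("MF and HF designed positions overlap")
  s0 <- make_structure(n_res, seed = seed)
  designed <- setNames(c(rep("MF", length(mf_positions)),
                         rep("HF", length(hf_positions))),
                       c(mf_positions, hf_positions))
  des <- design_sequence(s0, designed, em)
  receptor <- des$structure

  # conservation truth: invariant columns at a deterministic stride
  n_inv <- max(1L, round(invariant_frac * n_res))
  inv_cols <- with_rng_seed(seed + 7L, sort(sample.int(n_res, n_inv)))
  rate_classes <- rep("fast", n_res)
  rate_classes[inv_cols] <- "invariant"
  sim <- simulate_msa(n_leaves = n_leaves, rate_classes = rate_classes,
                      root_seq = sequence_of(receptor), seed = seed + 13L,
                      include_root = TRUE)

  complexes <- lapply(seq_len(n_complexes), function(k) {
    iface <- with_rng_seed(seed + 100L + k, {
      start <- sample.int(6, 1)
      sort(sample(seq(start, n_res, by = 5), 4))
    })
    make_complex(receptor, iface, seed = seed + 200L + k)
  })

  labels <- data.frame(
    position = as.integer(names(designed)),
    designed_frustration = unname(designed),
    stringsAsFactors = FALSE)
  labels$rate_class <- rate_classes[labels$position]
  labels$designed_conservation <-
    ifelse(labels$rate_class == "invariant", "C", "NC")
  labels$designed_class <- six_class(labels$designed_frustration,
                                     labels$designed_conservation)
  labels <- labels[order(labels$position), ]
  rownames(labels) <- NULL
  list(receptor = receptor, complexes = complexes, sim = sim,
       labels = labels, design_converged = des$converged)
}
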