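#' Construct an EnergyModel
#'
#' An `EnergyModel` bundles everything needed to score a residue: the
#' 20x20 symmetric residue-pair contact potential (dimensionless; lower
#' is more stabilizing), the contact rule (distance cutoff and minimum
#' within-chain sequence separation), the mutational-decoy policy, the
#' number of decoys drawn per residue, and the global random seed.
#'
#' @param pair_potential 20x20 symmetric numeric matrix with dimnames
#'   equal to the one-letter amino-acid codes.
#' @param contact_cutoff_A contact distance cutoff in angstroms.
#' @param min_seq_sep minimum within-chain positional separation.
#' @param decoy_policy `"composition"` draws decoy identities from the
#'   multiset of identities present in the scored model; `"uniform20"`
#'   draws uniformly over the 20 standard amino acids.
#' @param n_decoys number of mutational decoys per residue.
#' @param seed integer global seed; each residue derives its own
#'   reproducible stream from it.
#' @return an object of class `EnergyModel`.
#' @export
energy_model <- function(pair_potential,
                         contact_cutoff_A = 6.5,
                         min_seq_sep = 2L,
                         decoy_policy = c("composition", "uniform20"),
                         n_decoys = 2000L,
                         seed = 1L) {
  decoy_policy <- match.arg(decoy_policy)
  pair_potential <- as.matrix(pair_potential)
  if (!identical(dim(pair_potential), c(20L, 20L)))
    stop("pair_potential must be a 20x20 matrix")
  if (is.null(dimnames(pair_potential)) ||
      !setequal(rownames(pair_potential), AA20) ||
      !setequal(colnames(pair_potential), AA20))
    stop("pair_potential must have one-letter amino-acid dimnames")
  pair_potential <- pair_potential[AA20, AA20]
  if (max(abs(pair_potential - t(pair_potential))) > 1e-9)
    stop("pair_potential must be symmetric")
  if (n_decoys < 1) stop("n_decoys must be >= 1")
  structure(list(pair_potential = pair_potential,
                 contact_cutoff_A = contact_cutoff_A,
                 min_seq_sep = as.integer(min_seq_sep),
                 decoy_policy = decoy_policy,
                 n_decoys = as.integer(n_decoys),
                 seed = as.integer(seed)),
            class = "EnergyModel")
}

#' @export
print.EnergyModel <- function(x, ...) {
  cat("EnergyModel: ", x$decoy_policy, " decoys (N = ", x$n_decoys,
      "), contact cutoff ", x$contact_cutoff_A, " A, min separation ",
      x$min_seq_sep, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Read a 20x20 pair-potential matrix from a text file
#'
#' The format is whitespace-delimited with a one-letter header row and
#' a one-letter first column; lines starting with `#` are comments.
#'
#' @param path file path.
#' @return 20x20 symmetric numeric matrix ordered by [AA20].
#' @export
read_energy_matrix <- function(path) {
  m <- as.matrix(read.table(path, header = TRUE, row.names = 1,
                            comment.char = "#", check.names = FALSE))
  if (!setequal(rownames(m), AA20) || !setequal(colnames(m), AA20))
    stop("energy matrix must be 20x20 with one-letter amino-acid labels")
  m <- m[AA20, AA20]
  storage.mode(m) <- "double"
  m
}

#' Write a 20x20 pair-potential matrix to a text file
#' @param m 20x20 matrix with one-letter dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energy_matrix <- function(m, path) {
  df <- data.frame(m[AA20, AA20], check.names = FALSE)
  write.table(cbind(aa = AA20, df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Default energy model
#'
#' Loads the packaged hydropathy-derived quasichemical-style contact
#' potential (see `inst/extdata/contact_potential_kd.tsv`): the energy
#' of a contacting pair is minus the product of the partners'
#' min-max-scaled Kyte-Doolittle hydropathies, doubled, so burial of
#' mutually hydrophobic pairs is stabilizing and polar/charged pairs
#' are close to neutral. The matrix is a synthetic default in the
#' spirit of knowledge-based contact potentials and is user-replaceable
#' via `matrix_path`.
#'
#' @param matrix_path optional path to a replacement 20x20 matrix file.
#' @param ... further arguments passed to [energy_model()].
#' @return an `EnergyModel`.
#' @export
default_energy_model <- function(matrix_path = NULL, ...) {
  if (is.null(matrix_path))
    matrix_path <- system.file("extdata", "contact_potential_kd.tsv",
                               package = "frustrace", mustWork = TRUE)
  energy_model(read_energy_matrix(matrix_path), ...)
}

# Deterministic per-residue stream seed: mixes the global seed with the
# chain id and author residue number so adding or removing residues does
# not shift other residues' draws. Kept below 2^31.
residue_stream_seed <- function(seed, chain, resno) {
  h <- (as.double(seed) %% 2147483647) + 1
  for (ch in utf8ToInt(as.character(chain))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  h <- (h * 131 + (as.double(resno) %% 65521) + 65521) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary, deterministic RNG state, restoring
# the caller's state afterwards.
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
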