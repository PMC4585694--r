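#' @importFrom stats dist as.dist setNames quantile kmeans
#' @importFrom utils read.table write.table read.delim head
NULL

# The 20 standard amino acids, one-letter, fixed order used throughout.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3TO1 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
            GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
            MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
            SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

AA1TO3 <- setNames(names(AA3TO1), AA3TO1)

#' Construct a StructureModel
#'
#' A `StructureModel` is the cleaned polymer representation used by all
#' scoring functions: one row per residue, holding the author residue
#' number, the one-letter amino-acid code and the coordinates of the
#' representative interaction site (C-beta, or C-alpha for glycine and
#' residues lacking a C-beta atom). Hydrogens, waters, ions and other
#' hetero groups are never part of a StructureModel.
#'
#' @param residues data.frame with columns `chain`, `resno`, `aa`,
#'   `x`, `y`, `z`.
#' @param id character identifier.
#' @param source_model_index which model of a multi-model file was kept.
#' @return an object of class `StructureModel`.
#' @export
structure_model <- function(residues, id = "structure", source_model_index = 1L) {
  needed <- c("chain", "resno", "aa", "x", "y", "z")
  if (!all(needed %in% names(residues)))
    stop("residues must have columns: ", paste(needed, collapse = ", "))
  residues <- as.data.frame(residues)[, needed]
  residues$chain <- as.character(residues$chain)
  residues$resno <- as.integer(residues$resno)
  residues$aa <- as.character(residues$aa)
  bad <- !residues$aa %in% AA20
  if (any(bad))
    stop("non-standard amino-acid codes in residues: ",
         paste(unique(residues$aa[bad]), collapse = ", "))
  for (ch in unique(residues$chain)) {
    rn <- residues$resno[residues$chain == ch]
    if (length(rn) > 1 && any(diff(rn) <= 0))
      stop("residue numbers not strictly increasing in chain ", ch)
  }
  rownames(residues) <- NULL
  structure(list(id = id,
                 residues = residues,
                 source_model_index = as.integer(source_model_index)),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  ch <- chain_ids(x)
  cat("StructureModel '", x$id, "': ", nrow(x$residues), " residues in ",
      length(ch), " chain(s) [", paste(ch, collapse = ", "),
      "], model ", x$source_model_index, "\n", sep = "")
  invisible(x)
}

#' Chain identifiers of a StructureModel, in file order
#' @param s a StructureModel.
#' @return character vector of chain ids.
#' @export
chain_ids <- function(s) unique(s$residues$chain)

#' Number of residues in a StructureModel
#' @param s a StructureModel.
#' @export
n_residues <- function(s) nrow(s$residues)

#' Load and sanitize a PDB structure
#'
#' Reads a PDB file and returns a cleaned [structure_model()]: hetero
#' records (waters, ions, ligands) and hydrogens are discarded,
#' selenomethionine (MSE) is recoded as Met before the standard-20
#' filter, residues with any other non-standard code are dropped with a
#' warning, and for multi-model (NMR) files a single model is kept
#' (the first by default). Alternate locations are resolved to the
#' highest-occupancy conformer, ties broken by label order. The
#' representative interaction site of each residue is its C-beta atom,
#' falling back to C-alpha for glycine or when C-beta is missing.
#'
#' @param path path to a PDB file.
#' @param model_policy `"first"` to keep model 1, or `"index"` to keep
#'   the model given by `model_index`.
#' @param model_index model number kept when `model_policy = "index"`.
#' @return a `StructureModel`.
#' @export
load_structure <- function(path, model_policy = c("first", "index"),
                           model_index = 1L) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e)))
  keep_model <- if (model_policy == "first") 1L else as.integer(model_index)
  nmodels <- nrow(as.matrix(pdb$xyz))
  if (keep_model > nmodels)
    stop("model ", keep_model, " requested but file has ", nmodels, " model(s)")

  at <- pdb$atom
  xyz <- as.matrix(pdb$xyz)[keep_model, ]
  at$x <- xyz[seq(1, length(xyz), by = 3)]
  at$y <- xyz[seq(2, length(xyz), by = 3)]
  at$z <- xyz[seq(3, length(xyz), by = 3)]

  # polymer records only; MSE (selenomethionine, deposited as HETATM) is
  # recoded to MET before the 20-code filter
  is_mse <- at$resid == "MSE"
  at$resid[is_mse] <- "MET"
  at <- at[at$type == "ATOM" | is_mse, , drop = FALSE]
  if (nrow(at) == 0) stop("no polymer residues in '", path, "'")

  # strip hydrogens (element symbol H/D)
  elt <- at$elesy
  if (is.null(elt) || all(is.na(elt)))
    elt <- sub("^[0-9]*", "", trimws(at$elety))
  at <- at[!substr(trimws(elt), 1, 1) %in% c("H", "D"), , drop = FALSE]

  nonstd <- !(at$resid %in% names(AA3TO1))
  if (any(nonstd)) {
    warning("dropping non-standard residue(s): ",
            paste(unique(at$resid[nonstd]), collapse = ", "))
    at <- at[!nonstd, , drop = FALSE]
  }
  at <- at[trimws(at$elety) %in% c("CA", "CB"), , drop = FALSE]
  if (nrow(at) == 0) stop("no standard residues remaining in '", path, "'")

  # alternate locations: highest occupancy, ties by label order
  at$alt[is.na(at$alt)] <- ""
  key <- paste(at$chain, at$resno, at$insert, trimws(at$elety), sep = "\r")
  occ <- at$o
  occ[is.na(occ)] <- 1
  fileord <- seq_len(nrow(at))
  ord <- order(key, -occ, at$alt)
  at <- at[ord, , drop = FALSE]
  keep_alt <- !duplicated(key[ord])
  at <- at[keep_alt, , drop = FALSE]
  at <- at[order(fileord[ord][keep_alt]), , drop = FALSE]

  # one row per residue, in file order of first appearance
  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  first <- match(unique(rkey), rkey)
  res <- data.frame(chain = at$chain[first],
                    resno = as.integer(at$resno[first]),
                    aa = unname(AA3TO1[at$resid[first]]),
                    stringsAsFactors = FALSE)
  cb <- match(paste(unique(rkey), "CB", sep = "\r"),
              paste(rkey, trimws(at$elety), sep = "\r"))
  ca <- match(paste(unique(rkey), "CA", sep = "\r"),
              paste(rkey, trimws(at$elety), sep = "\r"))
  site <- ifelse(is.na(cb), ca, cb)
  if (any(is.na(site))) {
    warning("dropping residue(s) lacking both CA and CB atoms")
    keep <- !is.na(site)
    res <- res[keep, , drop = FALSE]
    site <- site[keep]
  }
  res$x <- at$x[site]
  res$y <- at$y[site]
  res$z <- at$z[site]

  # enforce strictly increasing author numbering within each chain
  keep <- rep(TRUE, nrow(res))
  for (ch in unique(res$chain)) {
    idx <- which(res$chain == ch)
    last <- -Inf
    for (i in idx) {
      if (res$resno[i] <= last) keep[i] <- FALSE else last <- res$resno[i]
    }
  }
  if (!all(keep)) {
    warning("dropping ", sum(!keep),
            " residue(s) breaking monotonic numbering (insertion codes?)")
    res <- res[keep, , drop = FALSE]
  }
  if (nrow(res) == 0) stop("no standard residues remaining in '", path, "'")

  structure_model(res, id = sub("\\.pdb$", "", basename(path)),
                  source_model_index = keep_model)
}

#' Restrict a StructureModel to a set of chains
#'
#' Coordinates and residue records of the kept chains are untouched;
#' this is how the unbound (target-removed) receptor is obtained from a
#' complex before rescoring.
#'
#' @param s a StructureModel.
#' @param keep character vector of chain ids to retain.
#' @return a `StructureModel` containing exactly the kept chains.
#' @export
extract_chains <- function(s, keep) {
  stopifnot(inherits(s, "StructureModel"))
  if (length(keep) == 0) stop("'keep' must name at least one chain")
  unknown <- setdiff(keep, chain_ids(s))
  if (length(unknown))
    stop("unknown chain id(s): ", paste(unknown, collapse = ", "))
  res <- s$residues[s$residues$chain %in% keep, , drop = FALSE]
  structure_model(res, id = s$id, source_model_index = s$source_model_index)
}

#' One-letter sequence of a chain
#'
#' @param s a StructureModel.
#' @param chain chain id; defaults to the first chain.
#' @return one-letter amino-acid string in residue order.
#' @export
sequence_of <- function(s, chain = chain_ids(s)[1]) {
  stopifnot(inherits(s, "StructureModel"))
  if (is.na(chain)) return("")
  paste(s$residues$aa[s$residues$chain == chain], collapse = "")
}

#' Residue-residue contact map
#'
#' Two residues are in contact when their representative sites lie
#' within `cutoff_A` angstroms. Within a chain, pairs closer in sequence
#' than `min_seq_sep` positions are excluded (the default removes i,i+1
#' neighbour pairs); inter-chain pairs are never filtered by sequence
#' separation.
#'
#' @param s a StructureModel.
#' @param cutoff_A distance cutoff in angstroms (default 6.5).
#' @param min_seq_sep minimum within-chain positional separation
#'   (default 2).
#' @return object of class `ContactMap`: a list with `pairs` (two-column
#'   data.frame of residue row indices, `i < j`), `cutoff_A` and
#'   `min_seq_sep`.
#' @export
contact_map <- function(s, cutoff_A = 6.5, min_seq_sep = 2L) {
  stopifnot(inherits(s, "StructureModel"), cutoff_A > 0, min_seq_sep >= 1)
  res <- s$residues
  n <- nrow(res)
  pairs <- data.frame(i = integer(0), j = integer(0))
  if (n >= 2) {
    d <- as.matrix(dist(res[, c("x", "y", "z")]))
    within <- d <= cutoff_A
    # author residue numbers define within-chain sequence separation
    same_chain <- outer(res$chain, res$chain, "==")
    sep <- abs(outer(res$resno, res$resno, "-"))
    ok <- within & (!same_chain | sep >= min_seq_sep)
    ok[lower.tri(ok, diag = TRUE)] <- FALSE
    idx <- which(ok, arr.ind = TRUE)
    pairs <- data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
    pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs, cutoff_A = cutoff_A,
                 min_seq_sep = as.integer(min_seq_sep)),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat("ContactMap: ", nrow(x$pairs), " contacts (cutoff ", x$cutoff_A,
      " A, min separation ", x$min_seq_sep, ")\n", sep = "")
  invisible(x)
}

#' Contact partners of each residue
#'
#' @param cm a ContactMap.
#' @param n total number of residues.
#' @return list of integer vectors; element `i` holds the residue row
#'   indices in contact with residue `i`.
#' @export
contact_neighbors <- function(cm, n) {
  nb <- vector("list", n)
  for (k in seq_len(n)) nb[[k]] <- integer(0)
  if (nrow(cm$pairs)) {
    sp1 <- split(cm$pairs$j, factor(cm$pairs$i, levels = seq_len(n)))
    sp2 <- split(cm$pairs$i, factor(cm$pairs$j, levels = seq_len(n)))
    for (k in seq_len(n)) nb[[k]] <- sort(c(sp1[[k]], sp2[[k]]))
  }
  nb
}

#' Write a StructureModel as a PDB file
#'
#' Emits one ATOM record per residue at the representative site (CB, or
#' CA for glycine), with TER records between chains. Used by the
#' synthetic-data generators and tests; reading the file back with
#' [load_structure()] reproduces the model.
#'
#' @param s a StructureModel.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "StructureModel"))
  res <- s$residues
  lines <- character(0)
  serial <- 0L
  for (ch in chain_ids(s)) {
    sub <- res[res$chain == ch, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      serial <- serial + 1L
      elety <- if (sub$aa[k] == "G") "CA" else "CB"
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s%4s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
        serial, elety, AA1TO3[sub$aa[k]], ch, sub$resno[k],
        sub$x[k], sub$y[k], sub$z[k], 1, 0, "C"))
    }
    lines <- c(lines, sprintf("TER   %5d      %4s %1s%4d",
                              serial + 1L, AA1TO3[sub$aa[nrow(sub)]], ch,
                              sub$resno[nrow(sub)]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
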