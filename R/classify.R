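# Six-class residue scheme: the cross-product of the frustration state
# {MF, N, HF} with the conservation state {C, NC}, assigned per residue
# and aggregated over an ensemble of complexes sharing one reference
# sequence (one conservation profile serves all complexes).

#' The six residue classes, in canonical order
#' @export
SIX_CLASSES <- c("(MF, C)", "(HF, C)", "(HF, NC)",
                 "(MF, NC)", "(N, C)", "(N, NC)")

#' Six-class label from the two per-residue states
#'
#' @param srlf_state character vector in `{MF, N, HF}`.
#' @param cons_state character vector in `{C, NC}` (recycled).
#' @return character vector of class labels, e.g. `"(MF, C)"`.
#' @export
six_class <- function(srlf_state, cons_state) {
  if (!all(srlf_state %in% c("MF", "N", "HF")))
    stop("srlf_state must be MF, N or HF")
  if (!all(cons_state %in% c("C", "NC")))
    stop("cons_state must be C or NC")
  sprintf("(%s, %s)", srlf_state, cons_state)
}

#' Map chain positions onto reference-sequence positions
#'
#' Global alignment (match +1, mismatch 0, gap -1, deterministic
#' traceback) of a chain sequence against the reference, returning for
#' every chain position the matching reference position or `NA` when
#' unaligned. When the alignment identity falls below `min_identity`
#' the mapping is refused (all `NA`) with a warning.
#'
#' @param chain_seq one-letter chain sequence.
#' @param reference one-letter reference sequence.
#' @param min_identity identity floor over aligned pairs (default 0.6).
#' @return integer vector of length `nchar(chain_seq)` with attribute
#'   `identity`.
#' @export
map_to_reference <- function(chain_seq, reference, min_identity = 0.6) {
  stopifnot(nchar(chain_seq) > 0, nchar(reference) > 0)
  sm <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  diag(sm) <- 1
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(chain_seq), Biostrings::AAString(reference),
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 1,
    type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  map <- rep(NA_integer_, nchar(chain_seq))
  cp <- rp <- 0L
  n_pair <- n_id <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") cp <- cp + 1L
    if (s[k] != "-") rp <- rp + 1L
    if (p[k] != "-" && s[k] != "-") {
      map[cp] <- rp
      n_pair <- n_pair + 1L
      if (p[k] == s[k]) n_id <- n_id + 1L
    }
  }
  identity <- if (n_pair == 0) 0 else n_id / n_pair
  if (identity < min_identity) {
    warning(sprintf(
      "alignment identity %.1f%% below the %.0f%% floor; mapping refused",
      100 * identity, 100 * min_identity))
    map[] <- NA_integer_
  }
  attr(map, "identity") <- identity
  map
}

#' Join frustration profiles with conservation into the six-class table
#'
#' Each complex's receptor chain is mapped onto the reference sequence
#' (the sequence indexing the conservation profile), its per-residue
#' frustration states are joined with the per-position conservation
#' states, and the resulting per-complex six-class assignments are
#' tallied per reference position. Conservation is computed once for
#' the reference and shared by all complexes. Unmapped residues are
#' reported separately, never silently dropped.
#'
#' @param profiles named list of `FrustrationProfile` objects, one per
#'   complex.
#' @param cons a `ConservationProfile` for the reference sequence.
#' @param receptor_chains receptor chain id per profile (recycled;
#'   default: each profile's first chain).
#' @param reference reference sequence; defaults to the one-letter
#'   sequence stored in `cons`.
#' @param min_identity mapping identity floor (see
#'   [map_to_reference()]).
#' @return a `ResidueClassTable`: list with `by_residue` (per-position
#'   counts `n_MF`, `n_N`, `n_HF`, `n_total`, consensus state and
#'   class), `per_complex` (long per-(residue, complex) table with
#'   `srlf`, `rvet` and class), `class_fractions` (per complex and
#'   pooled; each row set sums to 1) and `unmapped`.
#' @export
aggregate_classes <- function(profiles, cons, receptor_chains = NULL,
                              reference = NULL, min_identity = 0.6) {
  stopifnot(length(profiles) >= 1, inherits(cons, "ConservationProfile"))
  if (is.null(names(profiles)) || any(names(profiles) == ""))
    names(profiles) <- paste0("complex", seq_along(profiles))
  if (is.null(reference)) reference <- paste(cons$aa, collapse = "")
  if (is.null(receptor_chains))
    receptor_chains <- vapply(profiles, function(p) p$chain[1], "")
  receptor_chains <- rep_len(receptor_chains, length(profiles))

  long <- list()
  unmapped <- list()
  for (k in seq_along(profiles)) {
    pr <- profiles[[k]]
    pr <- pr[pr$chain == receptor_chains[k], , drop = FALSE]
    if (nrow(pr) == 0)
      stop("profile '", names(profiles)[k], "' has no residues in chain ",
           receptor_chains[k])
    mp <- map_to_reference(paste(pr$aa, collapse = ""), reference,
                           min_identity = min_identity)
    df <- data.frame(complex = names(profiles)[k],
                     chain = pr$chain, resno = pr$resno, aa = pr$aa,
                     ref_pos = mp, srlf = pr$srlf, state_frust = pr$state,
                     stringsAsFactors = FALSE)
    ok <- !is.na(df$ref_pos) & df$ref_pos %in% cons$position
    un <- df[!ok, , drop = FALSE]
    df <- df[ok, , drop = FALSE]
    idx <- match(df$ref_pos, cons$position)
    df$rvet <- cons$rvet[idx]
    df$state_cons <- cons$state[idx]
    df$class <- six_class(df$state_frust, df$state_cons)
    long[[k]] <- df
    unmapped[[k]] <- un
  }
  long <- do.call(rbind, long)
  unmapped <- do.call(rbind, unmapped)
  rownames(long) <- rownames(unmapped) <- NULL

  # per-reference-position ensemble counts and modal consensus
  consensus_of <- function(states) {
    tab <- table(factor(states, levels = c("MF", "N", "HF")))
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) "N" else top
  }
  by_res <- cons[, c("position", "aa", "rvet", "state")]
  names(by_res)[4] <- "state_cons"
  cnt <- function(st) vapply(by_res$position, function(p)
    sum(long$ref_pos == p & long$state_frust == st), 0L)
  by_res$n_MF <- cnt("MF")
  by_res$n_N <- cnt("N")
  by_res$n_HF <- cnt("HF")
  by_res$n_total <- by_res$n_MF + by_res$n_N + by_res$n_HF
  by_res$consensus_state <- vapply(by_res$position, function(p) {
    st <- long$state_frust[long$ref_pos == p]
    if (length(st) == 0) NA_character_ else consensus_of(st)
  }, "")
  by_res$consensus_class <- ifelse(
    is.na(by_res$consensus_state), NA_character_,
    six_class(ifelse(is.na(by_res$consensus_state), "N",
                     by_res$consensus_state), by_res$state_cons))

  # class-population fractions, per complex and pooled
  frac_of <- function(cls) {
    tab <- table(factor(cls, levels = SIX_CLASSES))
    as.numeric(tab) / length(cls)
  }
  cf <- do.call(rbind, lapply(split(long$class, long$complex), frac_of))
  cf <- rbind(cf, pooled = frac_of(long$class))
  cf <- data.frame(complex = rownames(cf), cf, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(cf) <- c("complex", SIX_CLASSES)
  rownames(cf) <- NULL

  structure(list(by_residue = by_res, per_complex = long,
                 class_fractions = cf, unmapped = unmapped,
                 reference = reference),
            class = "ResidueClassTable")
}

#' @export
print.ResidueClassTable <- function(x, ...) {
  cat("ResidueClassTable: ", nrow(x$by_residue), " reference positions, ",
      length(unique(x$per_complex$complex)), " complex(es), ",
      nrow(x$unmapped), " unmapped residue record(s)\n", sep = "")
  invisible(x)
}

#' Two-dimensional conservation-vs-frustration map
#'
#' Emits the per-(residue, complex) `(rvet, srlf)` point list and the
#' 2D histogram counting points in each of the six class regions; the
#' region counts agree with the class tallies of the underlying table.
#' A per-residue variant averaging srlf across complexes is included.
#'
#' @param x a `ResidueClassTable`.
#' @return list with `points`, `histogram` (class, count, fraction) and
#'   `points_by_residue`.
#' @export
two_d_map <- function(x) {
  stopifnot(inherits(x, "ResidueClassTable"))
  pts <- x$per_complex[, c("complex", "ref_pos", "aa", "rvet", "srlf",
                           "class")]
  tab <- table(factor(pts$class, levels = SIX_CLASSES))
  hist <- data.frame(class = SIX_CLASSES, count = as.integer(tab),
                     fraction = as.numeric(tab) / max(nrow(pts), 1),
                     stringsAsFactors = FALSE)
  agg <- stats::aggregate(srlf ~ ref_pos + aa + rvet, data = pts, FUN = mean)
  names(agg)[names(agg) == "srlf"] <- "mean_srlf"
  list(points = pts, histogram = hist,
       points_by_residue = agg[order(agg$ref_pos), ])
}

#' Restrict the class table to selected reference positions
#'
#' Used for focused reports such as the Met-residue or Leu-residue
#' sets of calmodulin.
#'
#' @param x a `ResidueClassTable`.
#' @param positions integer vector of reference positions.
#' @return data.frame: the `by_residue` rows for those positions.
#' @export
residue_report <- function(x, positions) {
  stopifnot(inherits(x, "ResidueClassTable"))
  unknown <- setdiff(positions, x$by_residue$position)
  if (length(unknown))
    stop("unknown reference position(s): ", paste(unknown, collapse = ", "))
  out <- x$by_residue[match(positions, x$by_residue$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
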