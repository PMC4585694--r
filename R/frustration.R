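# Single-residue mutational frustration: the native identity of a
# residue is compared, as a Z-score, against decoys in which only that
# residue's amino-acid identity is randomized while the geometry and
# every other identity stay native.

# Energy of residue i for every candidate identity: v[a] is the sum of
# pair-potential terms over i's contacts if i carried identity a.
candidate_energy_vector <- function(s, nb_i, em) {
  if (length(nb_i) == 0)
    return(setNames(numeric(20), AA20))
  partners <- s$residues$aa[nb_i]
  rowSums(em$pair_potential[, partners, drop = FALSE])
}

# Decoy identity pool under the model's policy: unique identities plus
# sampling weights. Composition draws from the multiset of identities
# present in the scored model (so bound runs use the complex
# composition, unbound runs the receptor composition).
decoy_pool <- function(s, em) {
  if (em$decoy_policy == "uniform20") {
    list(aa = AA20, w = rep(1 / 20, 20))
  } else {
    tab <- table(factor(s$residues$aa, levels = AA20))
    list(aa = AA20[tab > 0], w = as.numeric(tab[tab > 0]) / sum(tab))
  }
}

#' Native single-residue energy
#'
#' Sum of pair-potential contact energies of residue `i` over its
#' contact partners, including inter-chain contacts when the model is a
#' complex. A residue with no contacts has energy 0.
#'
#' @param s a StructureModel.
#' @param cm a ContactMap for `s`.
#' @param em an EnergyModel.
#' @param i residue row index into `s$residues`.
#' @return numeric energy.
#' @export
native_residue_energy <- function(s, cm, em, i) {
  stopifnot(i >= 1, i <= n_residues(s))
  nb <- contact_neighbors(cm, n_residues(s))[[i]]
  v <- candidate_energy_vector(s, nb, em)
  unname(v[s$residues$aa[i]])
}

#' Sampled mutational-decoy energies of a residue
#'
#' Draws `em$n_decoys` decoys, each replacing only residue `i`'s
#' identity (geometry and all neighbour identities fixed) with an
#' identity sampled under the decoy policy, and returns their energies.
#' The random stream is derived deterministically from the model seed
#' and the residue's chain id and number.
#'
#' @inheritParams native_residue_energy
#' @return numeric vector of `em$n_decoys` decoy energies.
#' @export
mutational_decoy_energies <- function(s, cm, em, i) {
  stopifnot(i >= 1, i <= n_residues(s))
  nb <- contact_neighbors(cm, n_residues(s))[[i]]
  v <- candidate_energy_vector(s, nb, em)
  pool <- decoy_pool(s, em)
  sseed <- residue_stream_seed(em$seed, s$residues$chain[i], s$residues$resno[i])
  draws <- with_rng_seed(sseed,
    sample(pool$aa, em$n_decoys, replace = TRUE, prob = pool$w))
  unname(v[draws])
}

#' SRLF index: Z-score of the native energy against decoys
#'
#' The single-residue-level frustration index is
#' `(mean(decoys) - E_native) / sd(decoys)` with the population
#' standard deviation (divide by N), so a native identity more
#' stabilizing than the decoy average scores positive (minimally
#' frustrated side). A zero decoy spread yields `srlf = 0` with the
#' degenerate flag set.
#'
#' @param e_native native-identity energy.
#' @param decoy_energies numeric vector of decoy energies (length >= 1).
#' @return list with `srlf`, `decoy_mean`, `decoy_sd`, `degenerate`.
#' @export
srlf_index <- function(e_native, decoy_energies) {
  if (length(decoy_energies) < 1) stop("need at least one decoy energy")
  m <- mean(decoy_energies)
  sdp <- sqrt(mean((decoy_energies - m)^2))
  if (sdp == 0) {
    list(srlf = 0, decoy_mean = m, decoy_sd = 0, degenerate = TRUE)
  } else {
    list(srlf = (m - e_native) / sdp, decoy_mean = m, decoy_sd = sdp,
         degenerate = FALSE)
  }
}

#' Exact SRLF index by decoy enumeration
#'
#' Deterministic counterpart of the sampled index: every candidate
#' identity is enumerated with its decoy-policy weight and the decoy
#' mean and population standard deviation are computed in closed form.
#'
#' @inheritParams native_residue_energy
#' @return list with `srlf`, `e_native`, `decoy_mean`, `decoy_sd`,
#'   `degenerate`.
#' @export
srlf_exhaustive <- function(s, cm, em, i) {
  stopifnot(i >= 1, i <= n_residues(s))
  nb <- contact_neighbors(cm, n_residues(s))[[i]]
  v <- candidate_energy_vector(s, nb, em)
  pool <- decoy_pool(s, em)
  vv <- unname(v[pool$aa])
  m <- sum(pool$w * vv)
  var <- sum(pool$w * vv^2) - m^2
  sdp <- sqrt(max(var, 0))
  e_nat <- unname(v[s$residues$aa[i]])
  if (sdp < 1e-12) {
    list(srlf = 0, e_native = e_nat, decoy_mean = m, decoy_sd = 0,
         degenerate = TRUE)
  } else {
    list(srlf = (m - e_nat) / sdp, e_native = e_nat, decoy_mean = m,
         decoy_sd = sdp, degenerate = FALSE)
  }
}

#' Classify an SRLF index
#'
#' Minimally frustrated (`MF`) above +1, highly frustrated (`HF`) below
#' -1, neutral (`N`) otherwise; the inequalities are strict, so the
#' boundary values +/-1 are neutral. Degenerate residues are neutral.
#'
#' @param srlf numeric vector of SRLF indices.
#' @param degenerate logical vector (recycled).
#' @return character vector in `{MF, N, HF}`.
#' @export
classify_srlf <- function(srlf, degenerate = FALSE) {
  out <- ifelse(srlf > 1, "MF", ifelse(srlf < -1, "HF", "N"))
  out[rep_len(degenerate, length(srlf))] <- "N"
  out
}

#' Per-residue frustration profile of a structure
#'
#' Computes the SRLF index and MF/N/HF state for every residue of a
#' cleaned structure (single chain or complex).
#'
#' @param s a StructureModel.
#' @param em an EnergyModel.
#' @param method `"sample"` for Monte-Carlo decoys (default),
#'   `"exact"` for closed-form decoy enumeration.
#' @param context `"bound"` or `"unbound"` label carried in the output.
#' @return a `FrustrationProfile`: data.frame with columns `chain`,
#'   `resno`, `aa`, `e_native`, `decoy_mean`, `decoy_sd`, `srlf`,
#'   `state`, `degenerate`, `context`.
#' @export
frustration_profile <- function(s, em, method = c("sample", "exact"),
                                context = "bound") {
  stopifnot(inherits(s, "StructureModel"), inherits(em, "EnergyModel"))
  method <- match.arg(method)
  cm <- contact_map(s, em$contact_cutoff_A, em$min_seq_sep)
  n <- n_residues(s)
  nb <- contact_neighbors(cm, n)
  pool <- decoy_pool(s, em)
  out <- s$residues[, c("chain", "resno", "aa")]
  out$e_native <- out$decoy_mean <- out$decoy_sd <- out$srlf <- numeric(n)
  out$degenerate <- logical(n)
  for (i in seq_len(n)) {
    v <- candidate_energy_vector(s, nb[[i]], em)
    e_nat <- unname(v[out$aa[i]])
    if (method == "sample") {
      sseed <- residue_stream_seed(em$seed, out$chain[i], out$resno[i])
      draws <- with_rng_seed(sseed,
        sample(pool$aa, em$n_decoys, replace = TRUE, prob = pool$w))
      z <- srlf_index(e_nat, unname(v[draws]))
    } else {
      vv <- unname(v[pool$aa])
      m <- sum(pool$w * vv)
      sdp <- sqrt(max(sum(pool$w * vv^2) - m^2, 0))
      z <- if (sdp < 1e-12)
        list(srlf = 0, decoy_mean = m, decoy_sd = 0, degenerate = TRUE)
      else
        list(srlf = (m - e_nat) / sdp, decoy_mean = m, decoy_sd = sdp,
             degenerate = FALSE)
    }
    out$e_native[i] <- e_nat
    out$decoy_mean[i] <- z$decoy_mean
    out$decoy_sd[i] <- z$decoy_sd
    out$srlf[i] <- z$srlf
    out$degenerate[i] <- z$degenerate
  }
  out$state <- classify_srlf(out$srlf, out$degenerate)
  out$context <- context
  out <- out[, c("chain", "resno", "aa", "e_native", "decoy_mean",
                 "decoy_sd", "srlf", "state", "degenerate", "context")]
  class(out) <- c("FrustrationProfile", "data.frame")
  out
}

#' Frustration profile of the receptor with targets removed
#'
#' Strips every chain not listed in `receptor_chains` from the complex
#' and recomputes the frustration profile of the remaining receptor, so
#' differences from the bound profile can be attributed to the binding
#' interface.
#'
#' @param s a StructureModel (complex).
#' @param receptor_chains chain ids kept as the receptor.
#' @inheritParams frustration_profile
#' @return a `FrustrationProfile` with `context = "unbound"`.
#' @export
unbound_profile <- function(s, receptor_chains, em,
                            method = c("sample", "exact")) {
  receptor <- extract_chains(s, receptor_chains)
  frustration_profile(receptor, em, method = match.arg(method),
                      context = "unbound")
}

#' Bound-vs-unbound frustration change
#'
#' Joins a bound and an unbound profile over the shared receptor
#' residues and reports per-residue SRLF changes and state transitions
#' on binding (e.g. `N->MF` means neutral unbound, minimally frustrated
#' bound).
#'
#' @param bound `FrustrationProfile` from the complex (receptor rows
#'   are selected by chain automatically).
#' @param unbound `FrustrationProfile` from the stripped receptor.
#' @return data.frame with `chain`, `resno`, `aa`, `srlf_bound`,
#'   `srlf_unbound`, `delta_srlf`, `state_bound`, `state_unbound`,
#'   `transition`.
#' @export
delta_frustration <- function(bound, unbound) {
  b <- bound[bound$chain %in% unique(unbound$chain), , drop = FALSE]
  kb <- paste(b$chain, b$resno)
  ku <- paste(unbound$chain, unbound$resno)
  if (!identical(sort(kb), sort(ku)))
    stop("bound and unbound profiles cover different receptor residues")
  u <- unbound[match(kb, ku), , drop = FALSE]
  out <- data.frame(chain = b$chain, resno = b$resno, aa = b$aa,
                    srlf_bound = b$srlf, srlf_unbound = u$srlf,
                    delta_srlf = b$srlf - u$srlf,
                    state_bound = b$state, state_unbound = u$state,
                    transition = ifelse(b$state == u$state, "unchanged",
                                        paste0(u$state, "->", b$state)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fixed-backbone variant rescoring of one position
#'
#' Replaces the amino-acid identity at one position in sequence only
#' (coordinates fixed) and recomputes the SRLF index of that position
#' under the same per-residue random stream, mimicking an in-silico
#' point mutation. The fold change is `|srlf_mut| / |srlf_wt|` and is
#' flagged undefined when the wild-type index is zero.
#'
#' @param s a StructureModel.
#' @param em an EnergyModel.
#' @param chain chain id of the mutated residue.
#' @param resno author residue number of the mutated residue.
#' @param new_aa one-letter code of the replacement identity.
#' @param method `"sample"` or `"exact"`.
#' @return list with `srlf_wt`, `srlf_mut`, `state_wt`, `state_mut`,
#'   `fold_change`, `fold_change_undefined`.
#' @export
variant_scan <- function(s, em, chain, resno, new_aa,
                         method = c("sample", "exact")) {
  method <- match.arg(method)
  if (!new_aa %in% AA20)
    stop("'", new_aa, "' is not a standard one-letter amino-acid code")
  i <- which(s$residues$chain == chain & s$residues$resno == resno)
  if (length(i) != 1)
    stop("position ", chain, ":", resno, " not found in structure")
  mut <- s
  mut$residues$aa[i] <- new_aa

  score_one <- function(model) {
    cm <- contact_map(model, em$contact_cutoff_A, em$min_seq_sep)
    if (method == "exact") {
      z <- srlf_exhaustive(model, cm, em, i)
      list(srlf = z$srlf, degenerate = z$degenerate)
    } else {
      e_nat <- native_residue_energy(model, cm, em, i)
      z <- srlf_index(e_nat, mutational_decoy_energies(model, cm, em, i))
      list(srlf = z$srlf, degenerate = z$degenerate)
    }
  }
  wt <- score_one(s)
  mt <- score_one(mut)
  undef <- wt$srlf == 0
  list(srlf_wt = wt$srlf, srlf_mut = mt$srlf,
       state_wt = classify_srlf(wt$srlf, wt$degenerate),
       state_mut = classify_srlf(mt$srlf, mt$degenerate),
       fold_change = if (undef) NA_real_ else abs(mt$srlf) / abs(wt$srlf),
       fold_change_undefined = undef)
}
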