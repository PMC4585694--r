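# build a conservation profile directly (scores + states chosen by hand)
fake_cons <- function(reference, rvet) {
  df <- data.frame(position = seq_len(nchar(reference)),
                   aa = strsplit(reference, "")[[1]],
                   column = seq_len(nchar(reference)),
                   rvet = rvet,
                   state = conservation_state(rvet),
                   stringsAsFactors = FALSE)
  class(df) <- c("ConservationProfile", "data.frame")
  df
}

# build a frustration profile directly from chosen srlf values
fake_profile <- function(seq, srlf, chain = "A") {
  df <- data.frame(chain = chain, resno = seq_len(nchar(seq)),
                   aa = strsplit(seq, "")[[1]],
                   e_native = 0, decoy_mean = 0, decoy_sd = 1,
                   srlf = srlf, state = classify_srlf(srlf),
                   degenerate = FALSE, context = "bound",
                   stringsAsFactors = FALSE)
  class(df) <- c("FrustrationProfile", "data.frame")
  df
}

test_that("six_class pairs the two states into six distinct labels", {
  expect_identical(six_class("MF", "C"), "(MF, C)")
  expect_identical(six_class("HF", "NC"), "(HF, NC)")
  combos <- expand.grid(f = c("MF", "N", "HF"), c = c("C", "NC"),
                        stringsAsFactors = FALSE)
  labels <- six_class(combos$f, combos$c)
  expect_length(unique(labels), 6)
  expect_setequal(labels, SIX_CLASSES)
  expect_error(six_class("XX", "C"), "MF, N or HF")
})

test_that("map_to_reference handles identity, offsets and the identity floor", {
  ref <- cam_sequence()
  m1 <- map_to_reference(ref, ref)
  expect_equal(unclass(m1)[seq_len(148)], 1:148, ignore_attr = TRUE)
  # chain missing the first 4 residues: position k maps to k + 4
  trunc <- substr(ref, 5, 148)
  m2 <- map_to_reference(trunc, ref)
  expect_equal(unclass(m2)[1:10], 5:14, ignore_attr = TRUE)
  expect_equal(attr(m2, "identity"), 1)
  # unrelated sequence: warning and an all-NA mapping
  expect_warning(m3 <- map_to_reference(strrep("W", 60), ref), "refused")
  expect_true(all(is.na(m3)))
})

test_that("aggregate reproduces designed x-out-of-y ensemble counts", {
  ref <- "ACDEFGHIKLMNPQRS"
  cons <- fake_cons(ref, rvet = rep(c(2, 8), 8))
  # residue 5 minimally frustrated in 53 of 58 complexes
  profiles <- lapply(seq_len(58), function(k) {
    z <- rep(0, nchar(ref))
    z[5] <- if (k <= 53) 1.6 else 0.2
    fake_profile(ref, z)
  })
  names(profiles) <- sprintf("c%02d", seq_len(58))
  tab <- aggregate_classes(profiles, cons)
  row5 <- tab$by_residue[tab$by_residue$position == 5, ]
  expect_equal(row5$n_MF, 53)
  expect_equal(row5$n_total, 58)
  expect_identical(row5$consensus_state, "MF")
  # single complex: counts are indicators
  tab1 <- aggregate_classes(profiles[1], cons)
  expect_true(all(tab1$by_residue$n_total == 1))
  # class fractions sum to 1 per complex and pooled
  frs <- as.matrix(tab$class_fractions[, SIX_CLASSES])
  expect_equal(unname(rowSums(frs)), rep(1, nrow(frs)))
  # order of complexes does not matter
  tab_rev <- aggregate_classes(rev(profiles), cons)
  expect_equal(tab_rev$by_residue$n_MF, tab$by_residue$n_MF)
})

test_that("modal consensus breaks ties toward neutral", {
  ref <- "ACDEFGHI"
  cons <- fake_cons(ref, rvet = rep(2, 8))
  profiles <- list(a = fake_profile(ref, c(1.5, rep(0, 7))),
                   b = fake_profile(ref, c(-1.5, rep(0, 7))))
  tab <- aggregate_classes(profiles, cons)
  expect_identical(tab$by_residue$consensus_state[1], "N")
})

test_that("stored classes recompute exactly from stored srlf and rvet", {
  em <- default_energy_model(seed = 2, n_decoys = 300)
  rec <- make_structure(30, seed = 3)
  profs <- list(x = frustration_profile(make_complex(rec, c(10, 20), seed = 1), em),
                y = frustration_profile(make_complex(rec, c(5, 25), seed = 2), em))
  cons <- fake_cons(sequence_of(rec), rvet = rep(c(1.5, 9), 15))
  tab <- aggregate_classes(profs, cons)
  pc <- tab$per_complex
  expect_identical(pc$class,
                   six_class(classify_srlf(pc$srlf),
                             conservation_state(pc$rvet)))
})

test_that("two_d_map region counts equal the class tallies", {
  ref <- "ACDEFGHIKL"
  cons <- fake_cons(ref, rvet = c(rep(2, 5), rep(8, 5)))
  profiles <- list(p1 = fake_profile(ref, c(2, -2, 0, 1.2, 0, 2, -2, 0, 0, 0)),
                   p2 = fake_profile(ref, rep(0, 10)))
  tab <- aggregate_classes(profiles, cons)
  tdm <- two_d_map(tab)
  tally <- table(factor(tab$per_complex$class, levels = SIX_CLASSES))
  expect_equal(tdm$histogram$count, as.integer(tally))
  expect_equal(sum(tdm$histogram$fraction), 1)
  # no residue below -1 in p2-only table -> empty HF regions
  tab2 <- aggregate_classes(profiles["p2"], cons)
  h2 <- two_d_map(tab2)$histogram
  expect_equal(h2$count[h2$class %in% c("(HF, C)", "(HF, NC)")], c(0L, 0L))
})

test_that("designed class proportions are recovered within binomial error", {
  # 3% of positions designed (HF, NC); the histogram should echo it
  nres <- 200
  ref <- paste(rep("A", nres), collapse = "")
  rvet <- rep(2, nres)
  z <- rep(0, nres)
  hf_nc <- seq_len(round(0.03 * nres))
  rvet[hf_nc] <- 9
  z[hf_nc] <- -2
  tab <- aggregate_classes(list(p = fake_profile(ref, z)),
                           fake_cons(ref, rvet))
  h <- two_d_map(tab)$histogram
  expect_equal(h$fraction[h$class == "(HF, NC)"], 0.03, tolerance = 0.01)
})

test_that("residue_report restricts to requested positions (Met and Leu sets)", {
  ref <- cam_sequence()
  cons <- fake_cons(ref, rvet = rep(2, 148))
  tab <- aggregate_classes(list(p = fake_profile(ref, rep(0, 148))), cons)
  met <- which(strsplit(ref, "")[[1]] == "M")
  leu <- which(strsplit(ref, "")[[1]] == "L")
  expect_equal(nrow(residue_report(tab, met)), 9)
  expect_equal(nrow(residue_report(tab, leu)), 9)
  expect_true(all(residue_report(tab, met)$aa == "M"))
  expect_equal(nrow(residue_report(tab, integer(0))), 0)
  expect_error(residue_report(tab, 999), "unknown")
})

test_that("unmapped residues are reported, not dropped", {
  ref <- "ACDEFGHIKLMNPQRSTVWY"
  cons <- fake_cons(ref, rvet = rep(2, 20))
  # chain carries 5 extra leading residues that cannot map
  chain_seq <- paste0("WWWWW", ref)
  prof <- fake_profile(chain_seq, rep(0, 25))
  tab <- aggregate_classes(list(p = prof), cons)
  expect_equal(nrow(tab$per_complex), 20)
  expect_equal(nrow(tab$unmapped), 5)
})
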