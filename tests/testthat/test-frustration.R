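test_that("native residue energy matches closed forms and the brute-force oracle", {
  em <- energy_model(identity_potential(), decoy_policy = "uniform20",
                     n_decoys = 100, seed = 1)
  # zero contacts -> 0
  lone <- structure_model(data.frame(chain = "A", resno = c(1, 50),
                                     aa = "A", x = c(0, 100), y = 0, z = 0))
  cm <- contact_map(lone)
  expect_equal(native_residue_energy(lone, cm, em, 1), 0)
  # one like-pair contact under the identity matrix -> -1
  pair <- structure_model(data.frame(chain = "A", resno = c(1, 5),
                                     aa = "A", x = c(0, 3), y = 0, z = 0))
  cm2 <- contact_map(pair)
  expect_equal(native_residue_energy(pair, cm2, em, 1), -1)
  # random 40-mer, arbitrary matrix, vs brute-force double loop
  emd <- default_energy_model(seed = 2)
  s <- make_structure(40, seed = 8)
  cm3 <- contact_map(s, emd$contact_cutoff_A, emd$min_seq_sep)
  for (i in c(1, 7, 20, 40))
    expect_equal(native_residue_energy(s, cm3, emd, i),
                 oracle_native_energy(s, emd, i))
})

test_that("degenerate decoy sets give srlf 0, neutral, flagged", {
  # all rows of the potential equal: every decoy energy equals the native
  flat <- matrix(-0.5, 20, 20, dimnames = list(AAs, AAs))
  em <- energy_model(flat, decoy_policy = "uniform20", n_decoys = 50, seed = 1)
  s <- make_structure(20, seed = 3)
  cm <- contact_map(s)
  d <- mutational_decoy_energies(s, cm, em, 10)
  expect_length(d, 50)
  expect_true(all(d == native_residue_energy(s, cm, em, 10)))
  z <- srlf_index(native_residue_energy(s, cm, em, 10), d)
  expect_equal(z$srlf, 0)
  expect_true(z$degenerate)
  expect_equal(classify_srlf(z$srlf, z$degenerate), "N")

  # homopolymer under the composition policy: decoy pool is one identity
  hp <- make_structure(20, seed = 1, sequence = strrep("L", 20))
  emc <- energy_model(identity_potential(), decoy_policy = "composition",
                      n_decoys = 40, seed = 2)
  cmh <- contact_map(hp)
  dh <- mutational_decoy_energies(hp, cmh, emc, 10)
  expect_true(all(dh == native_residue_energy(hp, cmh, emc, 10)))
  expect_true(srlf_exhaustive(hp, cmh, emc, 10)$degenerate)
})

test_that("srlf_index follows the Z-score definition with population sd", {
  expect_equal(srlf_index(0, c(-1, 1))$srlf, 0)
  expect_equal(srlf_index(-1, c(0, 2))$srlf, 2)  # (1 - (-1)) / sd_pop(=1)
  expect_error(srlf_index(0, numeric(0)), "at least one")
  # sign convention: stabilizing native identity scores positive
  expect_gt(srlf_index(-5, c(0, 1, 2))$srlf, 0)
})

test_that("exhaustive srlf reproduces the single-contact closed form", {
  em <- energy_model(identity_potential(), decoy_policy = "uniform20",
                     n_decoys = 10, seed = 1)
  pair <- structure_model(data.frame(chain = "A", resno = c(1, 5),
                                     aa = "A", x = c(0, 3), y = 0, z = 0))
  cm <- contact_map(pair)
  z <- srlf_exhaustive(pair, cm, em, 1)
  # decoys: 1/20 at -1, 19/20 at 0 -> mean -0.05, sd sqrt(0.05*0.95)
  expect_equal(z$decoy_mean, -0.05)
  expect_equal(z$decoy_sd, sqrt(0.05 * 0.95))
  expect_equal(z$srlf, (-0.05 + 1) / sqrt(0.05 * 0.95))
  expect_equal(round(z$srlf, 2), 4.36)
})

test_that("sampled srlf agrees with the exhaustive oracle and decoy moments are consistent", {
  for (policy in c("composition", "uniform20")) {
    em <- default_energy_model(seed = 5, n_decoys = 5000,
                               decoy_policy = policy)
    s <- make_structure(50, seed = 21)
    cm <- contact_map(s, em$contact_cutoff_A, em$min_seq_sep)
    for (i in seq_len(n_residues(s))) {
      ex <- srlf_exhaustive(s, cm, em, i)
      d <- mutational_decoy_energies(s, cm, em, i)
      sm <- srlf_index(native_residue_energy(s, cm, em, i), d)
      expect_lt(abs(sm$srlf - ex$srlf), 0.1)
      # sampled decoy mean within 3 Monte-Carlo standard errors of exact
      if (!ex$degenerate) {
        se <- ex$decoy_sd / sqrt(em$n_decoys)
        expect_lt(abs(mean(d) - ex$decoy_mean), 3.5 * se)
      }
    }
  }
})

test_that("profiles classify by strict +/-1 cutoffs and partition the states", {
  expect_identical(classify_srlf(c(1.5, -1.2, 0.3, 1, -1)),
                   c("MF", "HF", "N", "N", "N"))
  em <- default_energy_model(seed = 4, n_decoys = 300)
  s <- make_structure(40, seed = 13)
  pr <- frustration_profile(s, em)
  expect_s3_class(pr, "FrustrationProfile")
  expect_equal(nrow(pr), 40)
  expect_true(all(pr$state %in% c("MF", "N", "HF")))
  expect_identical(pr$state, classify_srlf(pr$srlf, pr$degenerate))
  # a residue designed to carry the best identity at its position is MF
  des <- design_sequence(s, setNames("MF", 20), em)
  pe <- frustration_profile(des$structure, em, method = "exact")
  expect_identical(pe$state[pe$resno == 20], "MF")
})

test_that("profiles are seed-deterministic and geometry-invariant", {
  em <- default_energy_model(seed = 17, n_decoys = 400)
  s <- make_structure(30, seed = 6)
  expect_identical(frustration_profile(s, em), frustration_profile(s, em))

  # rigid rotation + translation leaves all srlf untouched (same seeds)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(s$residues[, c("x", "y", "z")]) %*% R
  s2 <- s
  s2$residues$x <- xyz[, 1] + 11
  s2$residues$y <- xyz[, 2] - 3
  s2$residues$z <- xyz[, 3] + 5
  p1 <- frustration_profile(s, em)
  p2 <- frustration_profile(s2, em)
  expect_equal(p1$srlf, p2$srlf, tolerance = 1e-12)

  # chain renaming leaves exact-mode srlf unchanged
  s3 <- s
  s3$residues$chain <- "Q"
  expect_equal(frustration_profile(s, em, method = "exact")$srlf,
               frustration_profile(s3, em, method = "exact")$srlf)
})

test_that("more favorable native contacts never decrease srlf", {
  s <- make_structure(35, seed = 9)
  em <- default_energy_model(seed = 3)
  cm <- contact_map(s, em$contact_cutoff_A, em$min_seq_sep)
  for (i in c(5, 12, 18, 30)) {
    a <- s$residues$aa[i]
    pp <- em$pair_potential
    pp[a, ] <- pp[a, ] - 0.5
    pp[, a] <- t(pp[a, , drop = FALSE])
    em2 <- energy_model(pp, contact_cutoff_A = em$contact_cutoff_A,
                        min_seq_sep = em$min_seq_sep,
                        decoy_policy = em$decoy_policy,
                        n_decoys = em$n_decoys, seed = em$seed)
    expect_gte(srlf_exhaustive(s, cm, em2, i)$srlf + 1e-9,
               srlf_exhaustive(s, cm, em, i)$srlf)
  }
})

test_that("unbound profiles isolate the binding interface", {
  rec <- make_structure(30, seed = 2)
  em <- default_energy_model(seed = 9, decoy_policy = "uniform20",
                             n_decoys = 300)
  # target contacting exactly one receptor residue: only that native
  # energy changes between bound and unbound
  cpx1 <- make_complex(rec, 15, seed = 4)
  b <- frustration_profile(cpx1, em)
  u <- unbound_profile(cpx1, "A", em)
  ba <- b[b$chain == "A", ]
  expect_identical(ba$resno[ba$e_native != u$e_native], 15L)
  # receptor_chains = all chains reduces to the plain profile
  all_u <- unbound_profile(cpx1, c("A", "B"), em)
  expect_equal(all_u$srlf, b$srlf)
})

test_that("delta_frustration reports differences and labelled transitions", {
  rec <- make_structure(30, seed = 2)
  em <- default_energy_model(seed = 9, n_decoys = 300)
  cpx <- make_complex(rec, c(10, 20), seed = 3)
  b <- frustration_profile(cpx, em)
  u <- unbound_profile(cpx, "A", em)
  d <- delta_frustration(b, u)
  expect_equal(d$delta_srlf, d$srlf_bound - d$srlf_unbound)
  expect_true(all(d$transition[d$state_bound == d$state_unbound] ==
                  "unchanged"))
  lab <- d$transition[d$state_bound != d$state_unbound]
  if (length(lab))
    expect_true(all(grepl("^(MF|N|HF)->(MF|N|HF)$", lab)))
  # identical profiles -> all zero
  d0 <- delta_frustration(u, u)
  expect_true(all(d0$delta_srlf == 0))
  # residue-set mismatch errors
  expect_error(delta_frustration(b, u[-1, ]), "different receptor")
})

test_that("an interface contact engineered to stabilize raises srlf on binding", {
  rec <- make_structure(30, seed = 2)
  em <- default_energy_model(seed = 1, decoy_policy = "uniform20")
  # the target residue repeats position 15's native identity, so the
  # like-pair contact favours the native over the decoy pool
  wt <- rec$residues$aa[rec$residues$resno == 15]
  cpx <- make_complex(rec, 15, target_seq = strrep(wt, 3), seed = 7)
  d <- delta_frustration(frustration_profile(cpx, em, method = "exact"),
                         unbound_profile(cpx, "A", em, method = "exact"))
  expect_gt(d$delta_srlf[d$resno == 15], 0)
})

test_that("variant_scan rescoring behaves at identities and degenerate matrices", {
  s <- make_structure(25, seed = 5)
  em <- default_energy_model(seed = 8, n_decoys = 500)
  wt_aa <- s$residues$aa[s$residues$resno == 12]
  same <- variant_scan(s, em, "A", 12, wt_aa)
  expect_equal(same$srlf_mut, same$srlf_wt)
  expect_equal(same$fold_change, 1)

  flat <- matrix(-0.3, 20, 20, dimnames = list(AAs, AAs))
  emf <- energy_model(flat, n_decoys = 100, seed = 8)
  vs <- variant_scan(s, emf, "A", 12, "W", method = "exact")
  expect_equal(vs$srlf_mut, vs$srlf_wt)
  expect_true(vs$fold_change_undefined)

  expect_error(variant_scan(s, em, "A", 12, "X"), "standard")
  expect_error(variant_scan(s, em, "A", 999, "W"), "not found")

  # a designed-HF residue mutated to the energy-optimal identity flips to MF
  des <- design_sequence(s, setNames("HF", 12), em)
  emu <- default_energy_model(seed = 8, decoy_policy = "uniform20",
                              n_decoys = 500)
  best <- AAs[which.min(sapply(AAs, function(a) {
    t <- des$structure; t$residues$aa[t$residues$resno == 12] <- a
    cm <- contact_map(t, emu$contact_cutoff_A, emu$min_seq_sep)
    native_residue_energy(t, cm, emu, which(t$residues$resno == 12))
  }))]
  flip <- variant_scan(des$structure, emu, "A", 12, best, method = "exact")
  expect_identical(flip$state_wt, "HF")
  expect_identical(flip$state_mut, "MF")
})
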