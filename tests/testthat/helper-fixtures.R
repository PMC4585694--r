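# Shared fixtures and independent test oracles. Oracles here are coded
# from the definitions (brute force, closed forms), not by calling the
# implementation paths they check.

AAs <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# identity-matrix pair potential: -1 for like pairs, 0 otherwise
identity_potential <- function() {
  m <- matrix(0, 20, 20, dimnames = list(AAs, AAs))
  diag(m) <- -1
  m
}

# brute-force O(n^2) contact oracle, straight from the rules
oracle_contacts <- function(s, cutoff = 6.5, min_sep = 2) {
  res <- s$residues
  out <- NULL
  n <- nrow(res)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((res$x[i] - res$x[j])^2 + (res$y[i] - res$y[j])^2 +
                (res$z[i] - res$z[j])^2)
      if (d > cutoff) next
      if (res$chain[i] == res$chain[j] &&
          abs(res$resno[i] - res$resno[j]) < min_sep) next
      out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) data.frame(i = integer(0), j = integer(0)) else
    data.frame(i = out[, 1], j = out[, 2])
}

# brute-force native-energy oracle: double loop over oracle contacts
oracle_native_energy <- function(s, em, i) {
  pc <- oracle_contacts(s, em$contact_cutoff_A, em$min_seq_sep)
  e <- 0
  for (k in seq_len(nrow(pc))) {
    if (pc$i[k] == i)
      e <- e + em$pair_potential[s$residues$aa[i], s$residues$aa[pc$j[k]]]
    if (pc$j[k] == i)
      e <- e + em$pair_potential[s$residues$aa[i], s$residues$aa[pc$i[k]]]
  }
  unname(e)
}

# write raw PDB text lines for hand-built inputs
pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          occ = 1, record = "ATOM  ") {
  sprintf("%s%5d  %-3s%4s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
          record, serial, elety, resid, chain, resno, x, y, z, occ, 0,
          substr(elety, 1, 1))
}

# tree-cut partition oracle: remove the cut nodes from the edge list
# and read groups off the connected components containing each leaf
oracle_partition <- function(tr, cut_nodes) {
  ntip <- length(tr$tip.label)
  keep_edge <- !(tr$edge[, 1] %in% cut_nodes) &
               !(tr$edge[, 2] %in% cut_nodes)
  edges <- tr$edge[keep_edge, , drop = FALSE]
  nodes <- setdiff(seq_len(ntip + tr$Nnode), cut_nodes)
  comp <- setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- as.character(edges[e, 1]); b <- as.character(edges[e, 2])
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[a] <- comp[b] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  leafcomp <- comp[as.character(seq_len(ntip))]
  unname(lapply(split(tr$tip.label[seq_len(ntip)], leafcomp), sort))
}

# entropy oracle: plain frequency tables, natural log, gaps excluded
oracle_column_entropy <- function(chars) {
  chars <- chars[chars != "-"]
  if (length(chars) == 0) return(0)
  p <- as.numeric(table(chars)) / length(chars)
  -sum(p * log(p))
}
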