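# Independent pure-R oracles and shared fixtures for the test suite.
# These deliberately re-derive geometry and energies from the definitions
# (all-pairs scans, recursive enumeration) and never call the package's
# compiled routines.

r_adjacent <- function(p, q, kind) {
  d <- abs(p - q)
  if (kind == "fcc") all(d <= 1) && sum(d) == 2 else sum(d) == 1
}

# brute-force all-pairs contact scan
r_contacts <- function(coords, kind) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i + 1 && r_adjacent(coords[i, ], coords[j, ], kind))
        out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

r_hp_energy <- function(sequence, coords, kind) {
  res <- strsplit(sequence, "")[[1]]
  ct <- r_contacts(coords, kind)
  if (nrow(ct) == 0) return(0L)
  -sum(res[ct[, 1]] == "h" & res[ct[, 2]] == "h")
}

r_contact_energy <- function(sequence, coords, kind, mat) {
  res <- strsplit(sequence, "")[[1]]
  ct <- r_contacts(coords, kind)
  if (nrow(ct) == 0) return(0)
  sum(mat[cbind(res[ct[, 1]], res[ct[, 2]])])
}

# independent recursive walk enumeration (counts only)
r_count_walks <- function(n, kind) {
  offsets <- if (kind == "fcc") {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) == 2, , drop = FALSE]
  } else {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
          c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  }
  recurse <- function(path) {
    if (nrow(path) == n) return(1)
    cur <- path[nrow(path), ]
    total <- 0
    for (r in seq_len(nrow(offsets))) {
      nxt <- cur + offsets[r, ]
      if (!any(path[, 1] == nxt[1] & path[, 2] == nxt[2] & path[, 3] == nxt[3]))
        total <- total + recurse(rbind(path, nxt))
    }
    total
  }
  recurse(matrix(0L, 1, 3))
}

# deterministic pseudo-random sequences for a given walk index
hp_sequence_for <- function(n, i) {
  set.seed(1000L + i)
  paste(sample(c("h", "p"), n, replace = TRUE), collapse = "")
}

aa_sequence_for <- function(n, i) {
  set.seed(2000L + i)
  paste(sample(strsplit("acdefghiklmnpqrstvwy", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# the canonical one-contact square on the cubic lattice
square_conf <- function(sequence = "hhhh") {
  conformation(sequence,
               rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               "cubic")
}

straight_conf <- function(sequence, lattice = "cubic") {
  n <- nchar(sequence)
  step <- if (lattice == "fcc") c(1, 1, 0) else c(1, 0, 0)
  coords <- outer(0:(n - 1), step)
  conformation(sequence, coords, lattice)
}

# 2-letter h/p contact matrix equivalent to the HP100 model
hp_equiv_matrix <- function() {
  m <- matrix(c(-1, 0, 0, 0), 2, 2, dimnames = list(c("h", "p"), c("h", "p")))
  contact_matrix(m, name = "hp-equivalence")
}

random_conf <- function(n, lattice, seed) {
  set.seed(seed)
  random_self_avoiding_walk(hp_sequence_for(n, seed), lattice)
}
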