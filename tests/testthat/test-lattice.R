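# Lattice geometry, conformations, walks, and coordinate I/O.

test_that("adjacency follows the lattice definitions and is symmetric", {
  expect_true(are_adjacent(c(0, 0, 0), c(1, 0, 0), "cubic"))
  expect_false(are_adjacent(c(0, 0, 0), c(1, 1, 0), "cubic"))
  expect_true(are_adjacent(c(0, 0, 0), c(1, 1, 0), "fcc"))
  expect_false(are_adjacent(c(0, 0, 0), c(2, 0, 0), "fcc"))
  # symmetry and translation invariance on random integer pairs
  set.seed(42)
  for (kind in c("cubic", "fcc")) {
    for (rep in 1:50) {
      p <- sample(-10:10, 3, replace = TRUE)
      q <- p + sample(-2:2, 3, replace = TRUE)
      shift <- sample(-20:20, 3, replace = TRUE)
      if (kind == "fcc") {
        if (sum(p) %% 2 != 0) p[1] <- p[1] + 1L
        if (sum(q) %% 2 != 0) q[1] <- q[1] + 1L
        if (sum(shift) %% 2 != 0) shift[1] <- shift[1] + 1L
      }
      expect_identical(are_adjacent(p, q, kind), are_adjacent(q, p, kind))
      expect_identical(are_adjacent(p, q, kind),
                       are_adjacent(p + shift, q + shift, kind))
      expect_identical(are_adjacent(p, q, kind), r_adjacent(p, q, kind))
    }
  }
})

test_that("FCC points with odd coordinate sum are rejected", {
  expect_error(are_adjacent(c(1, 0, 0), c(0, 0, 0), "fcc"), "odd")
  expect_error(lattice_neighbors(c(1, 0, 0), "fcc"), "odd")
})

test_that("coordination numbers are 6 (cubic) and 12 (FCC) everywhere", {
  expect_equal(nrow(lattice_neighbors(c(0, 0, 0), "cubic")), 6)
  expect_equal(nrow(lattice_neighbors(c(0, 0, 0), "fcc")), 12)
  nb <- lattice_neighbors(c(5, -3, 2), "cubic")
  nb0 <- lattice_neighbors(c(0, 0, 0), "cubic")
  expect_setequal(apply(nb, 1, paste, collapse = ","),
                  apply(sweep(nb0, 2, c(5, -3, 2), "+"), 1, paste,
                        collapse = ","))
  for (kind in c("cubic", "fcc")) {
    off <- lattice_spec(kind)$neighbor_offsets
    # offsets closed under negation and each satisfies adjacency to origin
    expect_setequal(apply(off, 1, paste, collapse = ","),
                    apply(-off, 1, paste, collapse = ","))
    for (r in seq_len(nrow(off)))
      expect_true(are_adjacent(c(0, 0, 0), off[r, ], kind))
  }
})

test_that("conformation invariants are enforced with informative errors", {
  expect_error(
    conformation("hph", rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0)), "cubic"),
    "self-avoidance.*residue 3")
  expect_error(
    conformation("hph", rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)), "cubic"),
    "connectivity.*residues 2 and 3")
  expect_error(
    conformation("hp", rbind(c(0, 0, 0), c(1, 0, 0)), "fcc"),
    "parity.*residue 2")
  expect_error(conformation("hph", rbind(c(0, 0, 0), c(1, 0, 0)), "cubic"),
               "does not match")
  expect_true(is_valid_conformation(square_conf()))
})

test_that("contacts excludes consecutive pairs and matches brute force", {
  expect_equal(nrow(contacts(straight_conf("hhhhhh"))), 0)
  expect_equal(contacts(square_conf()),
               matrix(c(1L, 4L), 1, dimnames = list(NULL, c("i", "j"))))
  for (kind in c("cubic", "fcc")) {
    for (seed in 1:10) {
      conf <- random_conf(12, kind, seed)
      got <- contacts(conf)
      ref <- r_contacts(conf$coords, kind)
      expect_equal(unname(got), unname(ref), ignore_attr = TRUE)
      # translation invariance
      shifted <- conformation(conf$sequence,
                              sweep(conf$coords, 2, c(2, 4, 2), "+"),
                              conf$lattice)
      expect_equal(unname(contacts(shifted)), unname(got),
                   ignore_attr = TRUE)
    }
  }
})

test_that("random self-avoiding walks are valid, seeded, origin-anchored", {
  set.seed(7)
  w1 <- random_self_avoiding_walk("h", "cubic")
  expect_equal(nrow(w1$coords), 1)
  expect_equal(w1$coords[1, ], c(0L, 0L, 0L))

  set.seed(11); a <- random_self_avoiding_walk(strrep("hp", 24), "cubic")
  set.seed(11); b <- random_self_avoiding_walk(strrep("hp", 24), "cubic")
  expect_identical(a$coords, b$coords)

  for (kind in c("cubic", "fcc")) {
    set.seed(5)
    for (i in 1:1000) {
      w <- random_self_avoiding_walk(strrep("h", 48), kind)
      if (!is_valid_conformation(w)) fail(sprintf("invalid %s walk", kind))
      if (any(w$coords[1, ] != 0L)) fail("walk not anchored at origin")
    }
    succeed()
  }
})

test_that("walk enumeration matches counts and an independent recursion", {
  expect_equal(length(enumerate_walks(1, "cubic")), 1)
  expect_equal(length(enumerate_walks(2, "cubic", canonical = FALSE)), 6)
  expect_equal(length(enumerate_walks(2, "fcc", canonical = FALSE)), 12)
  for (kind in c("cubic", "fcc")) {
    for (n in 2:4) {
      full <- length(enumerate_walks(n, kind, canonical = FALSE))
      expect_equal(full, r_count_walks(n, kind),
                   info = sprintf("%s n=%d", kind, n))
      # the canonical quotient removes exactly the first-step factor
      k <- if (kind == "fcc") 12 else 6
      expect_equal(full / k, length(enumerate_walks(n, kind)))
    }
  }
  expect_equal(count_walks(4, "cubic", canonical = FALSE), 150)
  expect_error(enumerate_walks(13, "cubic"), "guard limit")
  expect_error(enumerate_walks(9, "fcc"), "guard limit")
})

test_that("conformation files round-trip bit-exactly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  for (kind in c("cubic", "fcc")) {
    conf <- random_conf(15, kind, 3)
    write_conformation(conf, path)
    back <- read_conformation(path)
    expect_identical(back$sequence, conf$sequence)
    expect_identical(back$coords, conf$coords)
    expect_identical(back$lattice$kind, conf$lattice$kind)
    # a second write of the reloaded conformation is byte-identical
    path2 <- withr::local_tempfile(fileext = ".tsv")
    write_conformation(back, path2)
    expect_identical(readLines(path), readLines(path2))
    expect_equal(hp_energy(back), hp_energy(conf))
  }
  expect_error(read_conformation(withr::local_tempfile(lines = "x\ty")),
               "lattice")
})

test_that("FCC Cartesian export places neighbours at unit distance", {
  conf <- random_conf(20, "fcc", 9)
  cart <- fcc_to_cartesian(conf)
  steps <- sqrt(rowSums(diff(cart)^2))
  expect_equal(steps, rep(1, 19), tolerance = 1e-12)
  ct <- contacts(conf)
  if (nrow(ct)) {
    d <- sqrt(rowSums((cart[ct[, 1], , drop = FALSE] -
                         cart[ct[, 2], , drop = FALSE])^2))
    expect_equal(d, rep(1, nrow(ct)), tolerance = 1e-12)
  }
  expect_error(fcc_to_cartesian(square_conf()), "FCC")
})
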