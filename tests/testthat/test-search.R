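# Cooling schedule, acceptance rules, structural objective, and the
# population search with its evaluation accounting.

test_that("the cooling schedule is geometric from 4000 with factor 0.9999", {
  p <- anneal_params()
  expect_equal(cooling_temperature(0, p), 4000)
  expect_equal(cooling_temperature(1, p), 3999.6)
  n <- c(0:10, 100, 1000, 10000)
  expect_true(all(diff(cooling_temperature(n, p)) < 0))
  expect_error(anneal_params(t0 = -1))
  expect_error(anneal_params(theta = 1))
})

test_that("Metropolis acceptance: equal/improving always, worsening at the
          Boltzmann rate", {
  p <- anneal_params()
  set.seed(1)
  expect_true(all(vapply(1:50, function(i) sa_accept(0, i, p), TRUE)))
  expect_true(all(vapply(1:50, function(i) sa_accept(-3, i, p), TRUE)))
  # dE = t0 at n = 0: empirical acceptance ~ exp(-1) within 3 s.e. of 1e5 draws
  set.seed(123)
  acc <- mean(vapply(1:1e5, function(i) sa_accept(4000, 0, p), TRUE))
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 1e5)
  expect_lt(abs(acc - exp(-1)), 3 * se)
  # late steps: worsening moves essentially never accepted
  set.seed(5)
  expect_false(any(vapply(1:200, function(i) sa_accept(50, 2e5, p), TRUE)))
})

test_that("structural distance is the per-residue Euclidean distance in the
          raw coordinate frame", {
  a <- straight_conf("hhhh")
  expect_equal(structural_distance(a, a, 1:4), rep(0, 4))
  b <- conformation("hhhh", sweep(a$coords, 2, c(3, 4, 0), "+"), "cubic")
  expect_equal(structural_distance(a, b, 2), 5)
  expect_equal(structural_distance(a, b, 3), structural_distance(b, a, 3))
  short <- conformation("hh", cbind(0:1, 0L, 0L), "cubic")
  expect_error(structural_distance(a, short, 1), "length")
})

test_that("the structural objective is the mean absolute distance change
          over the affected range", {
  best <- straight_conf("hhhh")
  before <- square_conf("hhhh")
  # null move: zero objective, accepted under both readings
  for (mode in c("previous", "monotone")) {
    r <- structural_objective(before, before, best, c(1, 4), sof_mode = mode)
    expect_equal(r$sof, 0)
    expect_true(r$accept)
  }
  # single-residue move m = 1: objective is the absolute distance change
  b2 <- before$coords; b2[4, ] <- c(1, 2, 0)
  after <- conformation("hhhh", b2, "cubic")
  d_before <- structural_distance(before, best, 4)
  d_after <- structural_distance(after, best, 4)
  expect_lt(d_after, d_before)      # the move approaches the best snapshot
  r <- structural_objective(before, after, best, c(4, 4))
  expect_equal(r$sof, abs(d_before - d_after))
  expect_true(r$accept)             # prev_sof = Inf accepts the first move
  expect_false(structural_objective(before, after, best, c(4, 4),
                                    prev_sof = 0)$accept)
  # monotone reading accepts because the distance to best decreased
  expect_true(structural_objective(before, after, best, c(4, 4),
                                   sof_mode = "monotone")$accept)
  expect_error(structural_objective(before, after, best, c(1, 3)),
               "affected_range")
})

test_that("sof recomputation matches an independent residue-wise recount
          on fuzzed pull moves", {
  set.seed(77)
  for (rep in 1:20) {
    conf <- random_conf(9, "cubic", 200 + rep)
    best <- random_conf(9, "cubic", 300 + rep)
    best <- conformation(conf$sequence, best$coords, "cubic")
    all_mv <- enumerate_pull_moves(conf)
    mv <- all_mv[[sample(length(all_mv), 1)]]
    out <- apply_pull_move(conf, mv)
    rng <- attr(out, "affected_range")
    r <- structural_objective(conf, out, best, rng)
    idx <- which(rowSums(out$coords != conf$coords) > 0)
    expect_true(all(idx >= rng[1] & idx <= rng[2]))
    manual <- mean(abs(
      sqrt(rowSums((conf$coords[rng[1]:rng[2], , drop = FALSE] -
                      best$coords[rng[1]:rng[2], , drop = FALSE])^2)) -
      sqrt(rowSums((out$coords[rng[1]:rng[2], , drop = FALSE] -
                      best$coords[rng[1]:rng[2], , drop = FALSE])^2))))
    expect_equal(r$sof, manual)
  }
})

test_that("population initialisation yields descended, elected members", {
  model <- energy_model("hp")
  seq48 <- load_benchmark("HP1")$sequence
  set.seed(42)
  st <- initialize_population(seq48, "cubic", model, firefly_params(N = 8))
  expect_length(st$population, 8)
  expect_true(all(vapply(st$population, is_valid_conformation, TRUE)))
  expect_true(all(st$init_evals > 0))
  expect_equal(st$energies[st$best_index], min(st$energies))
  # recorded energies match re-evaluation
  expect_equal(vapply(st$population, hp_energy, 0), st$energies)
  # local-minimum certificate for two members
  for (i in c(1, st$best_index)) {
    conf <- st$population[[i]]
    e0 <- st$energies[i]
    improving <- vapply(enumerate_pull_moves(conf), function(mv)
      hp_energy(apply_pull_move(conf, mv)) < e0 - 1e-12, TRUE)
    expect_false(any(improving))
  }
  set.seed(42)
  st2 <- initialize_population(seq48, "cubic", model, firefly_params(N = 8))
  expect_equal(st$energies, st2$energies)
  expect_identical(st$population[[3]]$coords, st2$population[[3]]$coords)
})

test_that("the search finds the exhaustive optimum of a toy chain and is
          seed-reproducible", {
  model <- energy_model("hp")
  res <- run_search("hhhh", "cubic", model,
                    ff = firefly_params(N = 4, T = 5, max_steps = 500),
                    seed = 1)
  expect_equal(res$best_energy, -1)
  expect_equal(hp_energy(res$best_conformation), res$best_energy)
  res2 <- run_search("hhhh", "cubic", model,
                     ff = firefly_params(N = 4, T = 5, max_steps = 500),
                     seed = 1)
  expect_equal(res2$oval_total, res$oval_total)
  expect_equal(res2$best_energy, res$best_energy)
  expect_identical(res2$trace, res$trace)
  expect_identical(res2$best_conformation$coords, res$best_conformation$coords)
})

test_that("evaluation accounting decomposes exactly into the closed form", {
  expect_equal(oval_closed_form(c(5, 5), k = 1, T = 15, t_prime = 3), 48)
  model <- energy_model("hp")
  cases <- expand.grid(N = c(2, 4, 8), T = c(3, 7, 15))
  for (r in seq_len(nrow(cases))) {
    res <- run_search("hhpphh", "cubic", model,
                      ff = firefly_params(N = cases$N[r], T = cases$T[r],
                                          max_steps = 100 + 7 * r),
                      seed = r)
    counted <- sum(res$counters$init_evals) + res$counters$energy_evals +
      res$counters$structural_evals + res$counters$reelection_evals
    expect_equal(res$oval_total, counted)
    expect_equal(res$oval_total,
                 oval_closed_form(res$counters$init_evals, res$oval$k,
                                  res$oval$T, res$oval$t_prime))
    # per-step identities
    K <- res$oval$steps
    expect_equal(res$counters$energy_evals, K)
    expect_equal(res$counters$structural_evals, (cases$N[r] - 1) * K)
    expect_equal(res$counters$reelection_evals,
                 (res$oval$k + 1) * (cases$N[r] - 1))
    expect_equal(K, res$oval$k * res$oval$T + res$oval$t_prime)
  }
})

test_that("elected energy at each boundary is the population minimum and a
          degenerate N = 1 population reduces to plain annealing", {
  model <- energy_model("hp")
  res <- run_search("hhpphh", "cubic", model,
                    ff = firefly_params(N = 4, T = 5, max_steps = 200),
                    seed = 11)
  expect_true(all(diff(order(res$trace$interval)) > 0))
  # final elected member is a population minimum
  expect_equal(res$energies[res$best_index], min(res$energies))
  expect_lte(res$best_energy, min(res$energies))

  one <- run_search("hhpphh", "cubic", model,
                    ff = firefly_params(N = 1, T = 5, max_steps = 300),
                    seed = 2)
  expect_equal(one$counters$structural_evals, 0)
  expect_equal(one$counters$reelection_evals, 0)
  expect_true(one$terminated_by %in% c("converged", "max_steps"))
})

test_that("both structural-acceptance readings run and are reproducible", {
  model <- energy_model("hp")
  for (mode in c("previous", "monotone")) {
    r1 <- run_search("hhpphh", "cubic", model,
                     ff = firefly_params(N = 4, T = 5, max_steps = 150,
                                         sof_mode = mode), seed = 3)
    r2 <- run_search("hhpphh", "cubic", model,
                     ff = firefly_params(N = 4, T = 5, max_steps = 150,
                                         sof_mode = mode), seed = 3)
    expect_equal(r1$oval_total, r2$oval_total)
    expect_equal(r1$best_energy, r2$best_energy)
  }
})

test_that("max_steps exhaustion and target stops are reported, not raised", {
  model <- energy_model("hp")
  res <- run_search(strrep("hp", 8), "cubic", model,
                    ff = firefly_params(N = 2, T = 5, max_steps = 23),
                    seed = 1)
  expect_equal(res$terminated_by, "max_steps")
  expect_equal(res$oval$steps, 23)
  tgt <- run_search("hhhh", "cubic", model,
                    ff = firefly_params(N = 4, T = 5, max_steps = 5000),
                    seed = 4, target_energy = -1)
  expect_equal(tgt$terminated_by, "target")
  expect_lte(tgt$best_energy, -1)
})

test_that("speed-up reproduces the published evaluation-count ratios", {
  expect_equal(speed_up(10, 10), 1)
  expect_equal(round(speed_up(74.57e6, 16.02e6), 1), 4.7)
  expect_equal(round(speed_up(6.02e6, 23.79e6), 1), 0.3)
  expect_error(speed_up(-1, 5), "positive")
  expect_error(speed_up(5, 0), "positive")
})

test_that("run summaries round-trip the full effective configuration", {
  res <- run_search("hhhh", "cubic", energy_model("hp"),
                    ff = firefly_params(N = 2, T = 5, max_steps = 50),
                    seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_run_summary(res, path)
  s <- jsonlite::read_json(path)
  expect_equal(s$best_energy, res$best_energy)
  expect_equal(s$oval_total, res$oval_total)
  expect_equal(s$config$seed, 9)
  expect_equal(s$config$N, 2)
  expect_equal(s$config$t0, 4000)
})
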