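test_that("effective distance matches per-hop closed forms on a chain", {
  ch <- chain_net(3)
  d <- effective_distance(ch, 1)
  expect_equal(unname(d[1]), 0)
  # hop 1->2 has transition probability 1, hop 2->3 has 1/2
  expect_equal(unname(d[2]), 1)
  expect_equal(unname(d[3]), 2 + log(2))
})

test_that("effective distance equals the exhaustive path oracle", {
  for (seed_id in c(41, 42, 43, 44)) {
    net <- rand_toy(6, seed = seed_id)
    seed <- if (seed_id %% 2 == 0) 1 else c(1, 2)
    expect_equal(unname(effective_distance(net, seed)),
                 path_effdist_oracle(net$weights, seed))
  }
  # isolated node is unreachable, not an error
  m <- chain_net(3)$weights
  m <- rbind(cbind(m, 0), 0)
  d <- effective_distance(toy_net(m), 1)
  expect_equal(unname(d[4]), Inf)
})

test_that("surrogate objective rewards containment monotonically", {
  net <- rand_toy(8, seed = 51)
  seed <- c(1, 2)
  cap <- effdist_cap(net)
  base <- surrogate_objective(net, seed, integer(0), cap = cap)
  d0 <- effective_distance(net, seed)
  expect_equal(base, mean(pmin(unname(d0[-(1:2)]), cap)))
  # exhaustive supersets on an 8-node toy: adding a node never decreases it
  for (k in 1:20) {
    set.seed(400 + k)
    s <- sample(3:8, 2)
    extra <- sample(setdiff(3:8, s), 1)
    expect_gte(surrogate_objective(net, seed, c(s, extra), cap = cap),
               surrogate_objective(net, seed, s, cap = cap) - 1e-12)
  }
  # full seed resection is maximal containment
  expect_equal(surrogate_objective(net, seed, seed, cap = cap), cap)
})

test_that("cutting the only bridge drives far nodes to the cap", {
  n <- 8
  m <- matrix(0, n, n)
  for (i in 1:3) for (j in 1:3) if (i != j) m[i, j] <- 0.7
  for (i in 5:8) for (j in 5:8) if (i != j) m[i, j] <- 0.7
  m[3, 4] <- m[4, 3] <- 0.7
  m[4, 5] <- m[5, 4] <- 0.7
  net <- toy_net(m)
  cap <- effdist_cap(net)
  cut <- surrogate_objective(net, 1, 4, cap = cap)
  d_cut <- effective_distance(apply_resection(net, 4), 1)
  expect_true(all(!is.finite(d_cut[5:8])))
  expect_gt(cut, surrogate_objective(net, 1, 8, cap = cap))
})

test_that("simulated annealing matches exhaustive search on small pools", {
  sa <- sa_config(n_prop_per_node = 30, restarts = 2, top_k = 3)
  n_match <- 0
  cases <- 0
  for (seed_id in 1:50) {
    n <- 8 + (seed_id %% 5)
    net <- rand_toy(n, seed = 900 + seed_id)
    seed <- 1
    pool <- khop_neighborhood(net, seed, 2)
    S <- 1 + (seed_id %% 3)
    if (S > length(pool)) next
    cases <- cases + 1
    cap <- effdist_cap(net)
    brute <- exhaustive_best_surrogate(net, seed, S, pool, cap)
    got <- optimize_resection(net, seed, S, sa_cfg = sa, pool = pool,
                              cap = cap, rng_seed = seed_id)
    if (isTRUE(all.equal(got$objectives[1], brute$value))) {
      n_match <- n_match + 1
    }
  }
  expect_gte(cases, 50 - 5)
  expect_equal(n_match, cases)
})

test_that("degenerate annealing cases reduce to direct answers", {
  net <- rand_toy(7, seed = 71)
  pool <- khop_neighborhood(net, 1, 2)
  full <- optimize_resection(net, 1, length(pool), pool = pool, rng_seed = 1)
  expect_equal(full$sets[[1]], pool)
  expect_error(optimize_resection(net, 1, length(pool) + 1, pool = pool),
               "pool")
  # a cut vertex between the seed and the rest is the best single resection
  m <- matrix(0, 5, 5)
  m[1, 2] <- m[2, 1] <- 0.9
  for (j in 3:5) { m[2, j] <- m[j, 2] <- 0.8 }
  m[3, 4] <- m[4, 3] <- 0.5
  cut <- toy_net(m)
  got <- optimize_resection(cut, 1, 1, sa_cfg = sa_config(10, restarts = 1),
                            rng_seed = 2)
  # total containment: either the cut vertex or the seed itself
  expect_equal(got$objectives[1], effdist_cap(cut))
  expect_true(got$sets[[1]] %in% c(1L, 2L))
  expect_true(list(2L) %in% got$sets)
})

test_that("SI evaluation selects the candidate that contains the epidemic", {
  n <- 9
  m <- matrix(0, n, n)
  for (i in 1:4) for (j in 1:4) if (i != j) m[i, j] <- 0.8
  for (i in 6:9) for (j in 6:9) if (i != j) m[i, j] <- 0.8
  m[4, 5] <- m[5, 4] <- 0.8
  m[5, 6] <- m[6, 5] <- 0.8
  net <- toy_net(m)
  cfg <- si_config(beta = 0.6, t0 = 30, T = 40, n_runs = 400, rng_seed = 3)
  seed <- c(1, 2)
  out <- evaluate_and_select(net, seed, list(c(5), c(9)), cfg)
  expect_equal(out$resected, 5L)
  single <- evaluate_and_select(net, seed, list(c(3, 4)), cfg)
  expect_equal(single$resected, c(3L, 4L))
  # a candidate containing the whole seed beats any leaky partial one
  out2 <- evaluate_and_select(net, seed, list(c(3, 9), seed), cfg)
  expect_equal(out2$resected, c(1L, 2L))
  expect_equal(out2$I_R, 0)
})

test_that("the resection curve is monotone and stops at full containment", {
  # seed {1,2,3}: node 1 carries all outflow to the periphery, so a
  # single-node resection already stops propagation
  m <- matrix(0, 8, 8)
  m[1, 2] <- m[2, 1] <- 0.9
  m[1, 3] <- m[3, 1] <- 0.9
  m[2, 3] <- m[3, 2] <- 0.9
  for (j in 4:8) { m[1, j] <- m[j, 1] <- 0.7 }
  for (i in 4:7) { m[i, i + 1] <- m[i + 1, i] <- 0.6 }
  net <- toy_net(m)
  cfg <- si_config(beta = 0.5, t0 = 20, T = 30, n_runs = 400, rng_seed = 5)
  cv <- resection_curve(net, c(1, 2, 3), cfg = cfg,
                        sa_cfg = sa_config(20, restarts = 2, top_k = 3),
                        rng_seed = 6)
  expect_equal(cv$R100$S, 1)
  expect_equal(cv$R100$resected, 1L)
  expect_equal(cv$R90$S, 1)
  expect_lt(cv$s90, 1)
  expect_true(all(diff(cv$table$I_R) <= 1e-12))
  expect_true(cv$R100$all_runs_zero)
  # re-simulating the reported R100 at 10x the runs stays at exactly zero
  recheck <- propagation_extent(net, c(1, 2, 3), cv$R100$resected,
                                si_config(beta = 0.5, t0 = 20, T = 30,
                                          n_runs = 4000, rng_seed = 11))
  expect_true(recheck$all_runs_zero)
})

test_that("the trivial full-seed resection closes the curve", {
  pat <- generate_patient(synthetic_patient_config(n_rois = 40,
                                                   n_sampled = 10,
                                                   rng_seed = 77))
  net <- threshold_network(pat$network, 0.1)
  cfg <- si_config(n_runs = 300, rng_seed = 8)
  cv <- resection_curve(net, pat$seed, cfg = cfg,
                        sa_cfg = sa_config(15, restarts = 1, top_k = 3),
                        rng_seed = 9)
  last <- cv$outcomes[[length(cv$outcomes)]]
  expect_equal(last$I_R, 0)
  expect_true(last$all_runs_zero)
  expect_lte(cv$R100$S, length(pat$seed))
  expect_true(cv$s100 <= 1)
  expect_true(is.null(cv$R90) || cv$s90 <= cv$s100)
})

test_that("seed statistics count incident links", {
  m <- matrix(0, 6, 6)
  iso <- toy_net(m)
  expect_equal(seed_stats(iso, 1:2)$E_RA, 0)
  net <- chain_net(5)
  ss <- seed_stats(net, c(1, 3))
  # node 1 has 1 link, node 3 has 2
  expect_equal(ss$kappa_RA, 1.5)
  expect_equal(ss$E_RA, 3)
  comp <- toy_net(matrix(0.4, 11, 11) - diag(0.4, 11))
  expect_equal(seed_stats(comp, 1:4)$E_RA, 40)
  expect_error(seed_stats(net, integer(0)), "nonempty")
})

test_that("resection curves export tables and summaries", {
  dir <- withr::local_tempdir()
  m <- matrix(0, 5, 5)
  m[1, 2] <- m[2, 1] <- 0.9
  for (j in 3:5) { m[2, j] <- m[j, 2] <- 0.8 }
  net <- toy_net(m)
  cfg <- si_config(beta = 0.5, t0 = 10, T = 15, n_runs = 200, rng_seed = 2)
  cv <- resection_curve(net, 1, cfg = cfg,
                        sa_cfg = sa_config(10, restarts = 1, top_k = 2),
                        rng_seed = 3)
  export_resection(cv, file.path(dir, "curve.tsv"),
                   file.path(dir, "summary.json"))
  tab <- read.table(file.path(dir, "curve.tsv"), header = TRUE, sep = "\t")
  expect_equal(tab$S, cv$table$S)
  js <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_equal(js$S_RA, 1)
  expect_equal(js$i_R1, cv$i_R1)
})
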