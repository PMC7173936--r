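test_that("accuracy handles perfect, reversed and symmetric headings", {
  expect_equal(accuracy(manual_run(matrix(0, 3, 4))), 1)
  expect_equal(accuracy(manual_run(matrix(pi, 3, 4))), -1)
  expect_equal(accuracy(manual_run(matrix(c(0, pi / 2, pi, 3 * pi / 2),
                                          1, 4))), 0)
  expect_error(accuracy(manual_run(matrix(numeric(0), 0, 4))), "frames")
})

test_that("polarization captures consensus and cancellation", {
  expect_equal(polarization(manual_run(matrix(0.7, 2, 6))), 1)
  two_groups <- manual_run(matrix(rep(c(0, pi), each = 3), 1, 6))
  expect_equal(polarization(two_groups), 0, tolerance = 1e-12)
})

test_that("random headings polarize at the finite-size floor", {
  # E|mean of N unit vectors| ~ sqrt(pi) / (2 sqrt(N)) for uniform headings
  set.seed(101)
  N <- 100
  phi <- matrix(runif(3000 * N, -pi, pi), 3000, N)
  expect_equal(polarization(manual_run(phi)), sqrt(pi) / (2 * sqrt(N)),
               tolerance = 0.02)
})

test_that("accuracy never exceeds polarization", {
  set.seed(102)
  for (rep in 1:5) {
    phi <- matrix(runif(200, -pi, pi) + rnorm(1), 10, 20)
    r <- manual_run(phi)
    expect_lte(accuracy(r), polarization(r) + 1e-12)
  }
})

test_that("raw avoidance counts agents outside all repulsion zones", {
  r <- manual_run(matrix(0, 4, 10), nrz = c(0, 0, 0, 0))
  expect_equal(raw_avoidance(r), 1)
  expect_equal(raw_avoidance(manual_run(matrix(0, 2, 10),
                                        nrz = c(10, 10))), 0)
  expect_equal(raw_avoidance(manual_run(matrix(0, 2, 10), nrz = c(5, 5))),
               0.5)
})

test_that("recomputed zone membership agrees with the recorded counts", {
  env <- env_random(15, 8, seed = 111)
  run <- simulate_flock(env, flock_params(k = 3), 25, r_inf = 0.1,
                        total_time = 5, burn_in = 1, record_every = 0.5,
                        seed = 112)
  expect_equal(raw_avoidance(run), raw_avoidance(run, env))
})

test_that("avoidance cannot increase when danger discs are added", {
  env_small <- env_random(6, 8, seed = 113)
  env_big <- manual_env(rbind(env_small$ds,
                              matrix(runif(20, 0, 8), ncol = 2)), 8)
  run <- simulate_flock(env_small, flock_params(k = 3), 25, r_inf = 0.1,
                        total_time = 5, burn_in = 1, record_every = 0.5,
                        seed = 114)
  expect_lte(raw_avoidance(run, env_big), raw_avoidance(run, env_small))
})

test_that("the avoidance ratio normalizes against the control", {
  expect_equal(avoidance_ratio(0.6, 0.6), 1)
  expect_equal(avoidance_ratio(0.9, 0.6), 1.5)
  expect_error(avoidance_ratio(0.5, 0), "undefined")
})

test_that("fitness is zero at the solitary reference and reduces to C at beta 0", {
  expect_equal(fitness(0, 1, 0), 0)
  expect_equal(fitness(0, 1, 5), 0)
  expect_equal(fitness(0.37, 1.2, 0), 0.37)
  expect_equal(fitness(0.5, 1.2, 2), 0.9)
})

test_that("responders have zero out-degree but can retain in-degree", {
  env <- env_random(40, 8, seed = 121)
  run <- simulate_flock(env, flock_params(k = 3), 40, r_inf = 0.1,
                        total_time = 10, burn_in = 5, record_every = 0.5,
                        seed = 122)
  found_resp <- FALSE
  for (f in seq_along(run$times)) {
    g <- run$g[f, ]
    net <- interaction_network(run, f)
    dout <- igraph::degree(net, mode = "out")
    expect_true(all(dout[g == 1] == 0))
    expect_true(all(dout <= run$params$k))
    found_resp <- found_resp || any(g == 1)
  }
  expect_true(found_resp)
})

test_that("without danger sites every agent uses all k slots socially", {
  env <- manual_env(matrix(numeric(0), 0, 2), 8)
  run <- simulate_flock(env, flock_params(k = 4), 30, r_inf = 0,
                        total_time = 3, burn_in = 1, record_every = 0.5,
                        seed = 123)
  for (f in seq_along(run$times)) {
    dout <- igraph::degree(interaction_network(run, f), mode = "out")
    expect_true(all(dout == 4))
  }
})

test_that("component counts match the flood-fill oracle on random graphs", {
  set.seed(131)
  for (rep in 1:30) {
    n <- sample(5:25, 1)
    m <- sample(0:(2 * n), 1)
    edges <- cbind(sample(n, m, TRUE), sample(n, m, TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    e3 <- if (nrow(edges) == 0) matrix(integer(0), 0, 3) else
      cbind(1L, edges[, 1], edges[, 2])
    run <- manual_run(matrix(0, 1, n), edges = e3)
    cs <- component_stats(run)
    oracle <- bf_components(n, edges)
    expect_equal(cs$n_components[1], length(oracle))
    expect_equal(sort(cs$sizes[[1]]), sort(oracle))
  }
})

test_that("edgeless and complete graphs have N and 1 components", {
  n <- 12
  expect_equal(component_stats(manual_run(matrix(0, 1, n),
               edges = matrix(integer(0), 0, 3)))$n_components, n)
  full <- t(combn(n, 2))
  expect_equal(component_stats(manual_run(matrix(0, 1, n),
               edges = cbind(1L, full[, 1], full[, 2])))$n_components, 1)
})

test_that("responder fractions follow their definitions", {
  # 5 agents: 2 responds to a site; 1 watches 2; 3 watches 4; 5 isolated
  g <- matrix(c(0L, 1L, 0L, 0L, 0L), 1, 5)
  edges <- cbind(1L, c(1L, 3L), c(2L, 4L))
  rf <- responder_fractions(manual_run(matrix(0, 1, 5), g = g,
                                       edges = edges))
  expect_equal(rf$r_d, 0.2)
  expect_equal(rf$r_i, 0.2)

  # no danger: both fractions vanish
  rf0 <- responder_fractions(manual_run(matrix(0, 1, 5),
                                        edges = cbind(1L, 1L, 2L)))
  expect_equal(c(rf0$r_d, rf0$r_i), c(0, 0))

  # everyone responding: r_d = 1 and nobody has out-edges
  rf1 <- responder_fractions(manual_run(matrix(0, 1, 5),
                                        g = matrix(1L, 1, 5),
                                        edges = matrix(integer(0), 0, 3)))
  expect_equal(c(rf1$r_d, rf1$r_i), c(1, 0))
})

test_that("the out-degree-zero mass tracks the direct-responder fraction", {
  env <- env_random(60, 10, seed = 141)
  run <- simulate_flock(env, flock_params(k = 6), 100, r_inf = 0.1,
                        total_time = 10, burn_in = 5, record_every = 0.5,
                        seed = 142)
  dt <- degree_table(run)
  mass0 <- sum(dt$count[dt$degree_out == 0]) / sum(dt$count)
  r_d <- responder_fractions(run)$r_d
  expect_gte(mass0 + 1e-12, r_d)
  expect_lt(mass0 - r_d, 0.05)
})

test_that("edge lifetimes average the maximal presence runs", {
  mk <- function(frames_per_edge, nf) {
    e <- do.call(rbind, lapply(seq_along(frames_per_edge), function(i)
      cbind(frames_per_edge[[i]], i, i + 10L)))
    manual_run(matrix(0, nf, 20), edges = cbind(e[, 1], e[, 2], e[, 3]),
               times = seq_len(nf))
  }
  # static network over 10 frames: one censored run of 10 frames
  expect_equal(edge_lifetime(mk(list(1:10), 10)), 10)
  expect_true(is.na(edge_lifetime(mk(list(1:10), 10),
                                  include_censored = FALSE)))
  # alternating presence: runs of a single frame
  expect_equal(edge_lifetime(mk(list(seq(1, 9, 2)), 10)), 1)
  # three edges with interior runs of 2, 3 and 1 frames: mean 2
  r <- mk(list(2:3, 4:6, 8), 10)
  expect_equal(edge_lifetime(r), 2)
  expect_equal(edge_lifetime(r, include_censored = FALSE), 2)
  # frame spacing scales lifetimes into time units
  r2 <- mk(list(2:3), 10); r2$times <- seq(0, 45, by = 5)
  expect_equal(edge_lifetime(r2), 10)
  expect_error(edge_lifetime(mk(list(1), 1)), "two recorded frames")
})

test_that("run summaries collect the scalar observables", {
  env <- env_random(10, 8, seed = 151)
  run <- simulate_flock(env, flock_params(k = 3), 20, r_inf = 0.2,
                        total_time = 5, burn_in = 1, record_every = 0.5,
                        seed = 152)
  s <- run_summary(run, a_control = 0.8, beta = 2)
  expect_equal(s$C, accuracy(run))
  expect_equal(s$A, raw_avoidance(run) / 0.8)
  expect_equal(s$F, s$C + 2 * (s$A - 1))
  expect_true(s$C_tilde >= s$C)
  expect_true(s$r_d >= 0 && s$r_d <= 1 && s$r_i >= 0 && s$r_i <= 1)
})

test_that("trajectories round-trip to long-format records", {
  env <- env_random(5, 8, seed = 161)
  run <- simulate_flock(env, flock_params(k = 2), 6, r_inf = 0.5,
                        total_time = 2, burn_in = 1, record_every = 0.5,
                        seed = 162)
  df <- run_to_df(run)
  expect_equal(nrow(df), length(run$times) * 6)
  expect_equal(df$phi[df$agent_id == 3], unname(run$phi[, 3]))
  stem <- tempfile()
  write_run(run, stem)
  expect_true(file.exists(paste0(stem, "_trajectory.csv")))
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"))
  expect_equal(meta$params$k, 2)
  expect_equal(meta$env$n_ds, 5)
})
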