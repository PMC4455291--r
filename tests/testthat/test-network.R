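rates <- default_learning_rates()

test_that("initialisation respects the convergence mask and seed", {
  net <- init_network(L = 4, N = 16, f_density = 0.5, seed = 3)
  expect_equal(dim(net$c), c(4L, 16L))
  # 16 within-class entries may be nonzero, 48 are structurally zero
  expect_equal(sum(net$class_mask), 16)
  expect_true(all(net$c[net$class_mask == 0] == 0))
  expect_true(all(net$c[net$class_mask == 1] > 0 & net$c[net$class_mask == 1] < 1))
  expect_true(all(net$d > 0 & net$d < 1))
  expect_true(all(net$f >= 0 & net$f <= 0.1))
  # f rows of non-existing branches are zero
  for (i in 1:4) expect_true(all(net$f[i, net$class_mask[i, ] == 0, ] == 0))
  expect_identical(net, init_network(L = 4, N = 16, f_density = 0.5, seed = 3))
  net0 <- init_network(L = 2, N = 4, f_density = 0, seed = 1)
  expect_true(all(net0$f == 0))
})

test_that("initialisation rejects malformed masks", {
  bad <- matrix(1, 2, 4)                     # sensors in two classes at once
  expect_error(init_network(L = 2, N = 4, class_mask = bad), "exactly one")
  expect_error(init_network(L = 3, N = 16), "multiple")
})

test_that("PG potentials are the weighted inputs", {
  net <- random_network(5)
  r <- rep(0, 16)
  expect_equal(pg_potentials(net, r), matrix(0, 4, 16), ignore_attr = TRUE)
  net$d[] <- 1
  r <- seq(0.05, 0.95, length.out = 16)
  p <- pg_potentials(net, r)
  expect_equal(p, matrix(r, 4, 16, byrow = TRUE), ignore_attr = TRUE)
  net$d[1, 1] <- 0.5
  expect_equal(pg_potentials(net, c(0.8, r[-1]))[1, 1], 0.4)
  expect_error(pg_potentials(net, c(1.5, r[-1])), "\\[0, 1\\]")
})

test_that("branch potentials follow the product-of-inhibition formula", {
  # single branch, hand evaluation
  net <- init_network(L = 1, N = 1, f_density = 1, seed = 1)
  net$c[1, 1] <- 0.5; net$d[1, 1] <- 0.5; net$f[1, 1, 1] <- 0.1
  r <- 0.8
  p <- pg_potentials(net, r)
  expect_equal(p[1, 1], 0.4)
  expect_equal(mc_branch_potentials(net, r, p)[1, 1], 0.5 * 0.8 * (1 - 0.04))
  # full inhibition: 16 factors of 0.9
  net16 <- init_network(L = 1, N = 16, f_density = 1, seed = 1)
  net16$c[] <- 1; net16$d[] <- 1; net16$f[] <- 0.1
  r <- rep(1, 16)
  mb <- mc_branch_potentials(net16, r, pg_potentials(net16, r))
  expect_equal(mb[1, 1], 0.9^16, tolerance = 1e-12)
  # no inhibition reduces to the masked linear map
  net2 <- random_network(7)
  net2$f[] <- 0
  r <- runif(16)
  mb2 <- mc_branch_potentials(net2, r, pg_potentials(net2, r))
  expect_equal(mb2, net2$c * rep(r, each = 4), ignore_attr = TRUE)
  expect_equal(mc_outputs(mb2), as.vector((net2$c * net2$class_mask) %*% r))
})

test_that("MC outputs sum branch potentials", {
  expect_equal(mc_outputs(matrix(c(0.1, 0.2, 0.3, 0.4), 1, 4)), 1.0)
  expect_equal(mc_outputs(matrix(0, 3, 5)), rep(0, 3))
  net <- random_network(2)
  net$c[] <- net$class_mask; net$f[] <- 0
  mb <- mc_branch_potentials(net, rep(1, 16), pg_potentials(net, rep(1, 16)))
  expect_equal(mc_outputs(mb), rep(4, 4))  # four unit branches per glomerulus
})

test_that("vectorised forward pass matches the scalar triple loop", {
  set.seed(101)
  for (rep in 1:100) {
    net <- random_network(rep, f_density = runif(1))
    r <- runif(16)
    mb <- mc_branch_potentials(net, r, pg_potentials(net, r))
    expect_lt(max(abs(mc_outputs(mb) - mc_outputs_bruteforce(net, r))), 1e-12)
  }
})

test_that("deprived weights follow the quadratic decay recurrence", {
  net <- random_network(9)
  c0 <- net$c
  r0 <- rep(0, 16)
  traj <- matrix(NA_real_, 41, 16)
  traj[1, ] <- net$c[cbind(rep(1:4, each = 4), 1:16)]
  cur <- net
  for (t in 1:40) {
    p <- pg_potentials(cur, r0)
    mb <- mc_branch_potentials(cur, r0, p)
    cur <- update_weights(cur, r0, mb, p)
    traj[t + 1, ] <- cur$c[cbind(rep(1:4, each = 4), 1:16)]
  }
  # independent iteration of c_{t+1} = c_t - gamma_b c_t^2
  oracle <- traj[1, ]
  for (t in 1:40) {
    oracle <- oracle - rates[["gamma_b"]] * oracle^2
    expect_lt(max(abs(traj[t + 1, ] - oracle)), 1e-12)
  }
  expect_true(all(diff(traj[, 1]) <= 0))
  expect_true(all(diff(diff(traj[, 1])) >= -1e-12)) # increments shrink
})

test_that("worked pure-decay values match hand iteration from one", {
  net <- init_network(L = 1, N = 1, seed = 1)
  net$c[1, 1] <- 1
  r0 <- 0
  p <- pg_potentials(net, r0); mb <- mc_branch_potentials(net, r0, p)
  net1 <- update_weights(net, r0, mb, p)
  expect_equal(net1$c[1, 1], 1 - 10^-0.7, tolerance = 1e-12)
  p <- pg_potentials(net1, r0); mb <- mc_branch_potentials(net1, r0, p)
  net2 <- update_weights(net1, r0, mb, p)
  expect_equal(net2$c[1, 1], 0.8004738 - 10^-0.7 * 0.8004738^2,
               tolerance = 1e-6)
})

test_that("small weights outlive a matched linear decay", {
  gb <- rates[["gamma_b"]]
  cq <- cl <- 0.05
  for (t in 1:50) {
    cq <- cq - gb * cq^2
    cl <- cl - gb * cl
  }
  expect_gt(cq, cl * 5)
})

test_that("zero weight with zero drive is a fixed point", {
  net <- init_network(L = 1, N = 1, seed = 1)
  net$c[1, 1] <- 0; net$d[1, 1] <- 0
  p <- pg_potentials(net, 0); mb <- mc_branch_potentials(net, 0, p)
  out <- update_weights(net, 0, mb, p)
  expect_identical(out$c[1, 1], 0)
  expect_identical(out$d[1, 1], 0)
})

test_that("weight boxes and mask zeros survive arbitrary update sequences", {
  set.seed(55)
  net <- random_network(13)
  for (t in 1:200) {
    r <- runif(16)
    p <- pg_potentials(net, r)
    mb <- mc_branch_potentials(net, r, p)
    net <- update_weights(net, r, mb, p)
    expect_true(all(net$c >= 0 & net$c <= 1))
    expect_true(all(net$d >= 0 & net$d <= 1))
    expect_true(all(net$c[net$class_mask == 0] == 0))
  }
  expect_identical(net$f, random_network(13)$f)  # f never adapts
})

test_that("process_sequence records pre-update outputs in order", {
  net <- random_network(21)
  vals <- matrix(runif(5 * 16), 5, 16)
  data <- tiny_response(vals)
  tr <- process_sequence(net, data, adapt = TRUE)
  # first recorded row must use the initial weights
  mb0 <- mc_branch_potentials(net, vals[1, ], pg_potentials(net, vals[1, ]))
  expect_equal(tr$mc_outputs[1, ], mc_outputs(mb0), ignore_attr = TRUE)
  expect_equal(nrow(tr$mc_outputs), 5L)
  # static limit: adapt = FALSE and f = 0 is a fixed linear map
  net$f[] <- 0
  tr2 <- process_sequence(net, data, adapt = FALSE)
  expect_equal(tr2$mc_outputs, vals %*% t(net$c * net$class_mask),
               ignore_attr = TRUE)
  expect_identical(tr2$net$c, net$c)
  expect_error(process_sequence(net, tiny_response(matrix(0.5, 3, 4))),
               "channel count")
})

test_that("a dropout fault drives the deprived weight down and it recovers", {
  net <- random_network(3)
  set.seed(77)
  vals <- matrix(runif(200 * 16, 0.4, 0.9), 200, 16)
  data <- tiny_response(vals)
  flt <- fault_spec(4, start = 51, stop = 121, mode = "dropout")
  tr <- process_sequence(net, data, adapt = TRUE, faults = list(flt),
                         record_weights = TRUE)
  c14 <- tr$c_traj[, 1, 4]
  expect_true(all(diff(c14[51:120]) <= 0))
  expect_lt(c14[120], c14[51])
  expect_gt(c14[200], c14[121])              # regrows once drive returns
})

test_that("silencing one input never decreases other branch potentials", {
  set.seed(202)
  for (rep in 1:20) {
    net <- random_network(rep + 400)
    r <- runif(16, 0.1, 1)
    k <- sample(16, 1)
    delta <- disinhibition_check(net, r, k)
    expect_true(all(delta[, -k] >= -1e-15))
    # brute force recomputation
    r1 <- r; r1[k] <- 0
    ref <- mc_branches_bruteforce(net, r1) - mc_branches_bruteforce(net, r)
    expect_lt(max(abs(delta[, -k] - ref[, -k])), 1e-12)
    # strict increase where the full inhibitory chain is active
    i <- which(net$class_mask[, k] == 1)
    active_j <- which(net$f[i, , k] > 0 & net$c[i, ] > 0 & r > 0)
    active_j <- setdiff(active_j, k)
    if (net$d[i, k] > 0 && length(active_j) > 0)
      expect_true(all(delta[i, active_j] > 0))
  }
  net <- random_network(1)
  net$f[] <- 0
  delta <- disinhibition_check(net, runif(16), 5)
  expect_true(all(delta[, -5] == 0))
})

test_that("network state round-trips through JSON", {
  net <- random_network(8)
  path <- file.path(tempdir(), "net.json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_equal(back$c, net$c, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$d, net$d, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$f, net$f, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$rates, net$rates, tolerance = 1e-12)
  r <- runif(16)
  expect_equal(mc_outputs(mc_branch_potentials(back, r, pg_potentials(back, r))),
               mc_outputs(mc_branch_potentials(net, r, pg_potentials(net, r))),
               tolerance = 1e-9)
})
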