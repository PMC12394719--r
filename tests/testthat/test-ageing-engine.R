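test_that("LARKS centres are minimum-image consistent", {
  tab <- forcefield_table()
  rec <- sequence_record("ONE", "Y", "protein")
  ann <- larks_annotation("ONE", 1, 1, e_dis = 1, e_str = 40)
  topo1 <- build_topology(list(rec), 1, tab, ann)
  cfg1 <- toy_config(matrix(c(2, 3, 4), 1), c(10, 10, 10))
  expect_equal(larks_centers(cfg1, topo1)[1, ], c(2, 3, 4))
  # symmetric linear segment: the midpoint
  rec3 <- sequence_record("TRI", "YYY", "protein")
  ann3 <- larks_annotation("TRI", 1, 3, e_dis = 1, e_str = 40)
  topo3 <- build_topology(list(rec3), 1, tab, ann3)
  cfg3 <- toy_config(cbind(c(4.6, 5.0, 5.4), 5, 5), c(10, 10, 10))
  expect_equal(larks_centers(cfg3, topo3)[1, ], c(5, 5, 5))
  # chain wrapped across the boundary: unwrap-then-wrap oracle
  wrapped <- cbind(c(9.8, 0.2, 0.6), 5, 5) # contiguous via the boundary
  cfgw <- toy_config(wrapped, c(10, 10, 10))
  ctr <- larks_centers(cfgw, topo3)[1, ]
  expect_true(all(ctr >= 0 & ctr < 10))
  expect_equal(ctr, c(0.2, 5, 5), tolerance = 1e-10)
  # centre is within one sigma of all member beads (minimum image)
  d <- abs(ctr[1] - wrapped[, 1]); d <- pmin(d, 10 - d)
  expect_true(all(d <= max(topo3$beads$sigma)))
})

test_that("nucleation needs >= 4 LARKS on pairwise-distinct chains", {
  topo <- point_larks_topology(5)
  op <- order_parameter_params(cutoff = 1.0)
  led <- larks_ledger(topo)
  box <- c(20, 20, 20)
  square <- rbind(c(5, 5, 5), c(5.6, 5, 5), c(5, 5.6, 5), c(5.6, 5.6, 5))
  # 4 disordered LARKS on 4 chains within cutoff: one cluster of 4
  centers <- rbind(square, c(15, 15, 15))
  cl <- detect_nucleation_clusters(centers, topo, op, led, box)
  expect_length(cl, 1)
  expect_equal(cl[[1]], 1:4)
  # only 3 proximal: below min_cluster, no cluster
  centers3 <- rbind(square[1:3, ], c(15, 15, 15), c(17, 17, 17))
  expect_length(detect_nucleation_clusters(centers3, topo, op, led, box), 0)
  # structured LARKS are not candidates for new nuclei
  led2 <- led; led2$state[1] <- "structured"
  expect_length(detect_nucleation_clusters(centers, topo, op, led2, box), 0)
})

test_that("four proximal LARKS sharing a chain are only three replicas: no nucleus", {
  tab <- forcefield_table()
  rec2 <- sequence_record("TWO", "YY", "protein") # two 1-residue LARKS per chain
  ann <- larks_annotation("TWO", c(1, 2), c(1, 2), e_dis = 1, e_str = 40)
  topo <- build_topology(list(rec2), 3, tab, ann) # 6 instances on 3 chains
  op <- order_parameter_params(cutoff = 1.0)
  led <- larks_ledger(topo)
  box <- c(20, 20, 20)
  centers <- rbind(c(5, 5, 5), c(5.6, 5, 5),      # chain 1, both LARKS
                   c(5, 5.6, 5), c(15, 15, 15),   # chain 2
                   c(5.6, 5.6, 5), c(17, 17, 17)) # chain 3
  expect_length(detect_nucleation_clusters(centers, topo, op, led, box), 0)
})

test_that("cluster detection is invariant under chain relabelling", {
  topo <- point_larks_topology(6)
  op <- order_parameter_params(cutoff = 1.0)
  led <- larks_ledger(topo)
  box <- c(20, 20, 20)
  set.seed(11)
  centers <- rbind(matrix(c(5, 5, 5), 4, 3, byrow = TRUE) +
                     matrix(runif(12, 0, 0.4), 4, 3),
                   c(12, 12, 12), c(18, 18, 18))
  cl <- detect_nucleation_clusters(centers, topo, op, led, box)
  perm <- c(3, 1, 4, 2, 6, 5)
  cl_p <- detect_nucleation_clusters(centers[perm, ], topo, op, led, box)
  # mapping back through the permutation yields the same member set
  expect_equal(sort(perm[cl_p[[1]]]), sort(cl[[1]]))
})

test_that("transitions are irreversible, chain-distinct and hit the energy window", {
  sys <- mini_larks_system(n_chains = 8, density = 700, seed = 2, e_str = 40)
  topo <- sys$topology
  led <- larks_ledger(topo)
  led2 <- apply_transition(led, c(1, 3, 5, 8), topo, sys$table, sys$dh, 300,
                           time_ps = 12)
  expect_equal(sum(led2$state == "structured"), 4)
  expect_equal(led2$events$time_ps, 12)
  expect_equal(led2$events$instances[[1]], c(1L, 3L, 5L, 8L))
  # re-transition is a logic error
  expect_error(apply_transition(led2, c(1, 2, 4, 6), topo, sys$table, sys$dh, 300),
               "logic error")
  # per-LARKS post-transition binding hits the configured target window
  kTbind <- function(a, partners, scale) {
    sum(vapply(partners, function(b)
      scale[a, b] * condage:::larks_pair_binding(topo, sys$table, sys$dh, a, b, 300),
      numeric(1)))
  }
  for (a in c(1, 3, 5, 8)) {
    post <- kTbind(a, setdiff(c(1, 3, 5, 8), a), led2$pair_scale)
    expect_gte(post, 30); expect_lte(post, 50)
  }
  # intra-chain pairs never strengthen: scale touches only distinct chains
  expect_true(all(diag(led2$pair_scale) == 1))
})

test_that("templated growth requires enough structured neighbours of one assembly", {
  topo <- point_larks_topology(6)
  op <- order_parameter_params(cutoff = 1.0, growth_min = 2)
  led <- larks_ledger(topo)
  led$state[1:4] <- "structured"
  led$assembly[1:4] <- 1L
  box <- c(20, 20, 20)
  near2 <- rbind(c(5, 5, 5), c(5.6, 5, 5), c(5, 5.6, 5), c(5.6, 5.6, 5),
                 c(5.3, 5.3, 5.5),  # touches several structured members
                 c(6.5, 5, 5))      # touches exactly one (5.6,5,5): not attached
  g <- growth_attachment(near2, topo, op, led, box)
  expect_length(g, 1)
  expect_equal(g[[1]]$instance, 5)
  expect_gte(length(g[[1]]$partners), 2)
  # no structured LARKS at all: empty result
  expect_length(growth_attachment(near2, topo, op, larks_ledger(topo), box), 0)
})

test_that("a single-chain system never ages and a zero-size cutoff blocks transitions", {
  sys1 <- mini_larks_system(n_chains = 1, density = 300, seed = 3)
  params <- integrator_params(dt = 0.01, friction = 0.5, temperature = 300, seed = 4)
  res1 <- ageing_run(sys1, params,
                     order_parameter_params(check_interval = 500), n_steps = 3000)
  expect_true(all(res1$curve$structured_fraction == 0))
  expect_equal(nrow(res1$events), 0)
  # a vanishing cutoff: no proximity, no transitions
  sys8 <- mini_larks_system(n_chains = 8, density = 700, seed = 2)
  res2 <- ageing_run(sys8, params,
                     order_parameter_params(cutoff = 1e-9, check_interval = 500),
                     n_steps = 3000)
  expect_true(all(res2$curve$structured_fraction == 0))
})

test_that("harder proximity criteria strictly slow nucleation on matched seeds", {
  params <- integrator_params(dt = 0.01, friction = 0.5, temperature = 300, seed = 5)
  sys <- mini_larks_system(n_chains = 8, density = 700, seed = 2)
  easy <- ageing_run(sys, params,
                     order_parameter_params(cutoff = 1.3, check_interval = 500),
                     n_steps = 30000)
  sys <- mini_larks_system(n_chains = 8, density = 700, seed = 2)
  hard <- ageing_run(sys, params,
                     order_parameter_params(cutoff = 0.8, check_interval = 500),
                     n_steps = 30000)
  lag_easy <- nucleation_lag_time(easy$events)
  lag_hard <- nucleation_lag_time(hard$events)
  if (is.na(lag_hard)) lag_hard <- Inf
  expect_false(is.na(lag_easy))
  expect_gt(lag_hard, lag_easy)
  expect_gte(tail(easy$curve$structured_fraction, 1),
             tail(hard$curve$structured_fraction, 1))
})
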