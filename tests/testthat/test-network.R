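test_that("the two-node seed is mutually dependent", {
  net <- grow_network(2, rng_seed = 1)
  ed <- network_edges(net)
  expect_equal(nrow(ed), 2)
  expect_setequal(paste(ed$dependee, ed$dependent), c("0 1", "1 0"))
})

test_that("growth is deterministic given the seed", {
  a <- grow_network(50, rng_seed = 1)
  b <- grow_network(50, rng_seed = 1)
  expect_identical(network_edges(a), network_edges(b))
  c <- grow_network(50, rng_seed = 2)
  expect_false(identical(network_edges(a), network_edges(c)))
})

test_that("grown networks satisfy the structural invariants", {
  for (seed in 1:4) {
    for (n in c(10, 50, 173)) {
      net <- grow_network(n, rng_seed = seed)
      # exactly one in- and one out-edge per added node
      expect_equal(nrow(network_edges(net)), 2 * (n - 2) + 2)
      # every non-seed node attaches to lower ids in both directions,
      # no self edges, inverse adjacency consistent, weakly connected
      expect_silent(validate_network(net, grown = TRUE))
      for (i in 3:n) {
        expect_true(any(net$dependees[[i]] < i - 1))
        expect_true(any(net$dependents[[i]] < i - 1))
      }
    }
  }
})

test_that("undersized networks are rejected", {
  expect_error(grow_network(1), class = "coageing_invalid_size")
  expect_error(grow_network(0), class = "coageing_invalid_size")
})

test_that("replicate_topology shares or regrows topologies", {
  net <- grow_network(100, rng_seed = 3)
  shared <- replicate_topology(net, "shared", cohort_size = 3)
  expect_length(shared, 3)
  expect_identical(network_edges(shared[[1]]), network_edges(shared[[3]]))

  rand <- replicate_topology(net, "randomized", cohort_size = 3, rng_seed = 5)
  expect_length(rand, 3)
  expect_true(all(vapply(rand, function(x) x$n_nodes, integer(1)) == 100))
  expect_false(identical(network_edges(rand[[1]]), network_edges(rand[[2]])))

  rand2 <- replicate_topology(net, "randomized", cohort_size = 3, rng_seed = 5)
  for (i in 1:3) {
    expect_identical(network_edges(rand[[i]]), network_edges(rand2[[i]]))
  }
})

test_that("edge-list round trip preserves the dependency structure", {
  net <- grow_network(40, rng_seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist(net, path)
  back <- read_edgelist(path)
  expect_identical(network_edges(back), network_edges(net))
})

test_that("hand-built toy networks have the advertised shape", {
  chain <- toy_network("chain", n = 3)
  expect_equal(chain$dependees, list(integer(0), 0L, 1L))
  motif <- toy_network("two_dependee")
  expect_equal(motif$dependees[[3]], c(0L, 1L))
  single <- toy_network("singleton")
  expect_equal(single$n_nodes, 1L)
  expect_equal(single$dependees, list(integer(0)))
})
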