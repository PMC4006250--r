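# Network representation, classification and generator construction.

test_that("classification assigns every reaction exactly one kind", {
  ex <- example_chain()
  rep10 <- classify_reactions(ex)
  counts <- table(rep10$reactions$kind)
  expect_equal(sum(counts[c("chain_forward", "chain_backward")]), 18L)
  expect_equal(sum(counts[c("bypass_forward", "bypass_backward")]), 2L)
  expect_false(rep10$flags$has_degradation)
  expect_true(rep10$flags$has_bypass)
  expect_false(rep10$flags$bypass_touches_soi)

  rep3 <- classify_reactions(chain_network(forward = c(1, 1),
                                           backward = c(1, 1)))
  expect_equal(sum(rep3$reactions$kind %in%
                     c("chain_forward", "chain_backward")), 4L)
  expect_false(any(rep3$flags$has_bypass, rep3$flags$has_degradation,
                   rep3$flags$has_synthesis))
})

test_that("self-loops, contradictions and broken chains are rejected", {
  expect_error(
    reaction_network(tibble::tibble(reactant = c("S1", "S2"),
                                    product = c("S2", "S2"),
                                    rate = 1)),
    "self-loop"
  )
  expect_error(
    classify_reactions(reaction_network(
      tibble::tibble(reactant = c("S1", "S2"), product = c("S2", "S3"),
                     rate = 1, kind = c("chain_forward", "chain_backward")),
      species = c("S1", "S2", "S3"), sois = c("S1", "S3")
    )),
    "classified"
  )
  # S2-S3 link missing entirely
  expect_error(
    classify_reactions(reaction_network(
      tibble::tibble(reactant = c("S1", "S3"), product = c("S2", "S4"),
                     rate = 1),
      species = paste0("S", 1:4), sois = c("S1", "S4")
    )),
    "not a linear chain"
  )
  # bimolecular among non-SOIs is unsupported
  expect_error(
    classify_reactions(reaction_network(
      tibble::tibble(reactant = c("S1", "S2 + S3"), product = c("S2", "S4"),
                     rate = 1),
      species = paste0("S", 1:4), sois = "S1"
    )),
    "unsupported reaction"
  )
})

test_that("generator matrices follow the column convention", {
  net <- chain_network(forward = c(1, 1), backward = c(1, 1))
  gen <- build_generator(net, absorbing = c("S1", "S3"))
  expect_equal(unname(gen$matrix[, "S2"]), c(1, -2, 1))
  expect_equal(unname(gen$matrix[, "S1"]), c(0, 0, 0))
  expect_equal(unname(gen$matrix[, "S3"]), c(0, 0, 0))

  # degradation: diagonal collects it, lumped row exposes it
  netd <- chain_network(forward = c(1, 1), backward = c(1, 1),
                        degradations = c(S2 = 2))
  gend <- build_generator(netd, absorbing = c("S1", "S3"),
                          lump_degradation = TRUE)
  expect_equal(gend$matrix["S2", "S2"], -4)
  expect_equal(gend$matrix["*deg*", "S2"], 2)
  expect_equal(sum(gend$matrix[, "S2"]), 0)    # closed with the lumped state

  gen4 <- build_generator(chain4_sym(), absorbing = c("S1", "S4"))
  expect_equal(unname(gen4$matrix[2:3, 2:3]),
               matrix(c(-2, 1, 1, -2), 2))
})

test_that("column sums vanish over the closed state space", {
  set.seed(401)
  for (n in c(4, 7, 10)) {
    net <- random_chain(n, n_degradation = 1L)
    gen <- build_generator(net, lump_degradation = TRUE)
    expect_lt(max(abs(colSums(gen$matrix))), 1e-12)
  }
})

test_that("inner rate matrix equals the generator restricted to the block", {
  expect_equal(unname(inner_rate_matrix(chain4_sym())$matrix),
               matrix(c(-2, 1, 1, -2), 2))
  expect_equal(unname(inner_rate_matrix(chain3(1, 2))$matrix),
               matrix(-3, 1, 1))

  set.seed(402)
  for (k in 1:5) {
    net <- random_chain(6, n_bypass = 1L)
    inn <- inner_rate_matrix(net)
    gen <- build_generator(net, absorbing = net$sois)
    expect_equal(inn$matrix,
                 gen$matrix[inn$species, inn$species, drop = FALSE])
  }

  # bypass leaving through a boundary appears only in the diagonal
  netb <- chain_network(forward = rep(1, 3), backward = rep(1, 3),
                        bypasses = tibble::tibble(from = 2L, to = 4L,
                                                  rate = 0.5))
  innb <- inner_rate_matrix(netb)
  expect_equal(innb$matrix["S2", "S2"], -2.5)
  expect_equal(innb$matrix["S3", "S2"], 1)
  genb <- build_generator(netb, absorbing = c("S1", "S4"))
  expect_equal(innb$matrix, genb$matrix[innb$species, innb$species])
})

test_that("pure chain inner matrices have real negative spectra", {
  set.seed(403)
  for (n in 3:10) {
    inn <- inner_rate_matrix(random_chain(n))
    ei <- eigvals_inner(inn)
    expect_true(all(abs(Im(ei$values)) < 1e-10))
    expect_true(all(Re(ei$values) < 0))
  }
})

test_that("n = 2 chains have no intermediates", {
  inn <- delaychain:::inner_block(chain_network(forward = 1, backward = 1),
                                  absorbing = c("S1", "S2"))
  expect_true(delaychain:::no_intermediates(inn))
  expect_error(inner_rate_matrix(chain_network(forward = 1, backward = 1)),
               NA)
})
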