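# Abridged-model construction: rates, labels, synthesis rewiring, history.

test_that("two-SOI abridgement emits 2 loops + 2 links with conserved rates", {
  ex <- example_chain()
  ab <- abridge(ex)
  expect_equal(nrow(ab$delayed), 4L)
  expect_equal(sort(table(ab$delayed$label), decreasing = TRUE),
               sort(table(c(rep("first_return", 2), rep("first_arrival", 2))),
                    decreasing = TRUE))
  # outgoing-rate conservation at each SOI, exact
  out_s0 <- sum(ab$delayed$rate[ab$delayed$reactant == "S0"])
  out_s9 <- sum(ab$delayed$rate[ab$delayed$reactant == "S9"])
  expect_equal(out_s0, 1, tolerance = 1e-12)
  expect_equal(out_s9, 0.7, tolerance = 1e-12)
  # rates are probability-weighted outgoing rates
  pp <- ab$probabilities
  expect_equal(ab$delayed$rate[ab$delayed$reactant == "S0" &
                                 ab$delayed$label == "first_return"],
               pp$p_r_1 * 1, tolerance = 1e-12)
  expect_equal(ab$delayed$rate[ab$delayed$reactant == "S0" &
                                 ab$delayed$label == "first_arrival"],
               pp$p_a_n * 1, tolerance = 1e-12)
})

test_that("direct SOI-SOI reactions are carried over verbatim", {
  net <- reaction_network(
    tibble::tibble(
      reactant = c("S1", "S2", "S2", "S3", "S1", "S3"),
      product  = c("S2", "S1", "S3", "S2", "S3", "S1"),
      rate     = c(1, 2, 1, 1, 0.3, 0.4)
    ),
    species = c("S1", "S2", "S3"), sois = c("S1", "S3")
  )
  ab <- abridge(net)
  expect_equal(nrow(ab$immediate), 2L)
  expect_equal(sort(ab$immediate$rate), c(0.3, 0.4))
  expect_equal(nrow(ab$delayed), 4L)
  # conservation now includes the immediate branch
  expect_equal(sum(ab$delayed$rate[ab$delayed$reactant == "S1"]) +
                 sum(ab$immediate$rate[ab$immediate$reactant == "S1"]),
               1.3, tolerance = 1e-12)
})

test_that("single-SOI abridgement has one loop per outgoing reaction", {
  ex <- example_chain()
  ab1 <- abridge(ex, sois = "S9", mode = "single_soi")
  expect_equal(nrow(ab1$delayed), 1L)
  expect_equal(ab1$delayed$label, "first_return")
  expect_equal(ab1$delayed$rate, 0.7, tolerance = 1e-12)
  expect_equal(ab1$delayed$probability, 1, tolerance = 1e-10)

  # the single-SOI first-return law counts walks through the far end, so it
  # differs from the two-SOI loop at the same species
  ab2 <- abridge(ex)
  d_two <- ab2$delayed$delay[[which(ab2$delayed$reactant == "S9" &
                                      ab2$delayed$label == "first_return")]]
  d_one <- ab1$delayed$delay[[1]]
  expect_gt(dist_gap(d_one, d_two), 0.01)
})

test_that("n = 2 chains abridge to themselves", {
  net <- chain_network(forward = 1, backward = 0.5)
  ab <- abridge(net)
  expect_equal(nrow(ab$delayed), 0L)
  expect_equal(nrow(ab$immediate), 2L)
  expect_equal(sort(ab$immediate$rate), c(0.5, 1))
})

test_that("SOI-touching bypasses are rejected unless the extension is on", {
  net <- chain_network(forward = rep(1, 4), backward = rep(1, 4),
                       bypasses = tibble::tibble(from = 1L, to = 4L,
                                                 rate = 0.5))
  expect_error(abridge(net), "unsupported configuration")
  ab <- abridge(net, allow_soi_bypass = TRUE)
  expect_equal(sum(ab$delayed$rate[ab$delayed$reactant == "S1"]), 1.5,
               tolerance = 1e-12)
})

test_that("synthesis rewiring weights rates by arrival probabilities", {
  net <- chain_network(forward = c(1, 1), backward = c(2, 2),
                       syntheses = c(S2 = 3))
  ab <- abridge(net)
  syn <- ab$delayed[ab$delayed$label == "synthesis_arrival", ]
  expect_equal(nrow(syn), 2L)
  expect_equal(sort(syn$rate), c(1, 2), tolerance = 1e-12)   # (1/3)k, (2/3)k
  for (i in 1:2) {
    expect_equal(syn$delay[[i]]$rep$type, "stage_rates")
    expect_equal(syn$delay[[i]]$rep$rates, 3)                # Exp(3) delay
  }
  # SOI-producing synthesis is carried over verbatim
  nets <- chain_network(forward = c(1, 1), backward = c(2, 2),
                        syntheses = c(S1 = 5))
  abs_ <- abridge(nets)
  expect_true(any(abs_$immediate$product == "S1" &
                    abs_$immediate$reactant == "" &
                    abs_$immediate$rate == 5))
  expect_equal(sum(abs_$delayed$label == "synthesis_arrival"), 0L)
})

test_that("degradation inside the block becomes a delayed loss branch", {
  net <- chain_network(forward = c(1, 1), backward = c(1, 1),
                       degradations = c(S2 = 2))
  ab <- abridge(net)
  loss <- ab$delayed[ab$delayed$label == "loss", ]
  expect_equal(nrow(loss), 2L)
  expect_equal(loss$rate[loss$reactant == "S1"], 0.5, tolerance = 1e-12)
  # conservation still exact including the loss branch
  expect_equal(sum(ab$delayed$rate[ab$delayed$reactant == "S1"]), 1,
               tolerance = 1e-12)
})

test_that("initial history draws outcomes and times from the closed forms", {
  # all mass on SOIs: nothing pending
  ex <- example_chain()
  ab <- abridge(ex)
  h0 <- build_initial_history(ex, ab, c(S9 = 200))
  expect_equal(nrow(h0$pending), 0L)
  expect_equal(h0$discarded, 0L)
  expect_equal(unname(h0$initial_state["S9"]), 200)

  # 100 molecules on S2 of the n=3 chain: ~2/3 to S1, times Exp(3)
  net <- chain3(1, 2)
  ab3 <- abridge(net)
  set.seed(603)
  h <- build_initial_history(net, ab3, c(S2 = 1000))
  frac_s1 <- mean(h$pending$product == "S1")
  expect_lt(abs(frac_s1 - 2 / 3), 3 * sqrt(2 / 9 / 1000))
  ks <- ks_compare(h$pending$time, delay_stages(3))
  expect_true(ks$pass)
  expect_true(!is.unsorted(h$pending$time))

  # certain degradation: everything discarded
  netd <- chain_network(forward = c(1, 0), backward = c(0, 1),
                        degradations = c(S2 = 2))
  abd <- abridge(netd)
  hd <- build_initial_history(netd, abd, c(S2 = 1))
  expect_equal(nrow(hd$pending), 0L)
  expect_equal(hd$discarded, 1L)

  expect_error(build_initial_history(net, ab3, c(Q = 1)), "not in the model")
})
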