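# Closed-form delay distributions, probabilities and the numeric oracle.

test_that("inner eigenvalues: values, simplicity, dissipativity", {
  expect_equal(sort(Re(eigvals_inner(matrix(c(-2, 1, 1, -2), 2))$values)),
               c(-3, -1))
  expect_true(eigvals_inner(matrix(c(-2, 1, 1, -2), 2))$simple)

  # uni-directional 4-stage chain, equal rates: eigenvalue -2 with
  # multiplicity 4 -> not simple
  K <- diag(-2, 4)
  K[cbind(2:4, 1:3)] <- 2
  ei <- eigvals_inner(K)
  expect_false(ei$simple)
  expect_equal(unique(round(Re(ei$values), 9)), -2)

  expect_error(eigvals_inner(matrix(c(0, 0, 0, -1), 2)), "dissipative")

  set.seed(501)
  for (k in 1:5) {
    inn <- inner_rate_matrix(random_chain(8))
    ei <- eigvals_inner(inn)
    expect_true(all(Re(ei$values) < 0))
    expect_true(all(abs(Im(ei$values)) < 1e-10))
  }
})

test_that("arrival/return/degradation probabilities match closed forms", {
  pp <- arrival_return_probabilities(inner_rate_matrix(chain3(1, 2)))
  expect_equal(pp$p_a_n, 1 / 3, tolerance = 1e-12)
  expect_equal(pp$p_r_1, 2 / 3, tolerance = 1e-12)

  # gambler's ruin: symmetric chain, start next to one end
  for (n in 4:7) {
    net <- chain_network(forward = rep(1, n - 1), backward = rep(1, n - 1))
    pp <- arrival_return_probabilities(inner_rate_matrix(net))
    expect_equal(pp$p_a_n, 1 / (n - 1), tolerance = 1e-12)
    # independent brute-force absorption solve on the embedded jump chain
    inn <- inner_rate_matrix(net)
    m <- length(inn$species)
    P <- t(abs(inn$matrix) / rep(-diag(inn$matrix), each = m))
    diag(P) <- 0
    b <- delaychain:::channel_beta(inn, net$sois[2]) / (-diag(inn$matrix))
    h <- solve(diag(m) - P, b)
    expect_equal(pp$p_a_n, unname(h[1]), tolerance = 1e-10)
  }

  ppd <- arrival_return_probabilities(inner_rate_matrix(chain3(1, 1, deg = 2)))
  expect_equal(ppd$p_a_n, 0.25, tolerance = 1e-12)
  expect_equal(ppd$p_r_1, 0.25, tolerance = 1e-12)
  expect_equal(ppd$p_deg_1, 0.5, tolerance = 1e-12)
})

test_that("probability conservation holds for random chains", {
  set.seed(502)
  for (k in 1:10) {
    n <- sample(3:9, 1)
    net <- random_chain(n, n_degradation = sample(0:2, 1),
                        n_bypass = if (n >= 5 && runif(1) < 0.5) 1L else 0L)
    pp <- arrival_return_probabilities(inner_rate_matrix(net))
    expect_lt(abs(pp$p_r_1 + pp$p_a_n + pp$p_deg_1 - 1), 1e-10)
    expect_lt(abs(pp$p_r_n + pp$p_a_1 + pp$p_deg_n - 1), 1e-10)
  }
})

test_that("single-intermediate delays are the total-rate exponential", {
  inn <- inner_rate_matrix(chain3(1, 2))
  fa <- first_arrival_distribution(inn, "toward_sn")
  fr <- first_return_distribution(inn, "s1")
  expect_equal(distribution_cdf(fa, log(2) / 3), 0.5, tolerance = 1e-12)
  expect_equal(distribution_cdf(fr, log(2) / 3), 0.5, tolerance = 1e-12)
  tt <- seq(0, 3, length.out = 50)
  expect_equal(distribution_cdf(fa, tt), 1 - exp(-3 * tt), tolerance = 1e-12)
})

test_that("symmetric 4-chain arrival is the Exp(1)*Exp(3) convolution", {
  fa <- first_arrival_distribution(inner_rate_matrix(chain4_sym()),
                                   "toward_sn")
  expect_equal(fa$rep$type, "stage_rates")
  expect_equal(sort(fa$rep$rates), c(1, 3))
  expect_equal(distribution_mean(fa), 4 / 3, tolerance = 1e-12)
  expect_lt(sup_vs_oracle(chain4_sym()), 1e-8)
})

test_that("bypass chains: residue forms match the matrix-exponential oracle", {
  set.seed(503)
  for (k in 1:5) {
    net <- random_chain(sample(5:9, 1), n_bypass = sample(1:2, 1))
    expect_lt(sup_vs_oracle(net), 1e-8)
  }
})

test_that("complex eigenvalue pairs still give real, proper CDFs", {
  set.seed(504)
  found <- FALSE
  for (k in 1:40) {
    net <- random_chain(sample(6:10, 1), n_bypass = 2L)
    inn <- inner_rate_matrix(net)
    ei <- eigvals_inner(inn)
    if (all(abs(Im(ei$values)) < 1e-9)) next
    found <- TRUE
    fa <- first_arrival_distribution(inn, "toward_sn")
    tt <- seq(0, 5 / min(abs(Re(ei$values))), length.out = 200)
    Fv <- distribution_cdf(fa, tt)
    expect_true(all(diff(Fv) > -1e-9))
    expect_true(all(Fv >= 0 & Fv <= 1))
    expect_lt(sup_vs_oracle(net), 1e-8)
    if (k > 10 && found) break
  }
  expect_true(found)
})

test_that("direction independence without bypasses; return laws differ", {
  set.seed(505)
  for (k in 1:5) {
    net <- random_chain(sample(4:9, 1))
    inn <- inner_rate_matrix(net)
    gap <- dist_gap(first_arrival_distribution(inn, "toward_sn"),
                    first_arrival_distribution(inn, "toward_s1"))
    expect_lt(gap, 1e-10)
  }
  # asymmetric n=6 chain: F_r,1 != F_r,n while F_a,n = F_a,1
  net <- chain_network(forward = c(3, 1, 2, 0.7, 1.2),
                       backward = c(0.4, 2, 1, 1.5, 0.8))
  inn <- inner_rate_matrix(net)
  expect_gt(dist_gap(first_return_distribution(inn, "s1"),
                     first_return_distribution(inn, "sn")), 0.01)
  expect_lt(dist_gap(first_arrival_distribution(inn, "toward_sn"),
                     first_arrival_distribution(inn, "toward_s1")), 1e-10)
})

test_that("degradation changes probabilities; closed expressions stay exact", {
  # adding killing shifts the arrival/return probabilities, but the closed
  # expressions need no modification: evaluated at the eigenvalues of the
  # degradation-inclusive inner matrix they still match the oracle exactly
  set.seed(506)
  for (k in 1:5) {
    n <- sample(4:8, 1)
    net <- random_chain(n)
    netd <- chain_network(
      forward = vapply(seq_len(n - 1), function(i) {
        r <- net$reactions
        r$rate[r$reactant == paste0("S", i) & r$product == paste0("S", i + 1)]
      }, numeric(1)),
      backward = vapply(seq_len(n - 1), function(i) {
        r <- net$reactions
        r$rate[r$reactant == paste0("S", i + 1) & r$product == paste0("S", i)]
      }, numeric(1)),
      degradations = setNames(runif(1, 0.5, 2), paste0("S", sample(2:(n - 1), 1)))
    )
    inn <- inner_rate_matrix(net)
    innd <- inner_rate_matrix(netd)
    p0 <- arrival_return_probabilities(inn)
    pd <- arrival_return_probabilities(innd)
    expect_gt(p0$p_a_n, pd$p_a_n)          # probabilities do change
    expect_gt(pd$p_deg_1, 0)
    expect_lt(abs(pd$p_r_1 + pd$p_a_n + pd$p_deg_1 - 1), 1e-10)
    expect_lt(sup_vs_oracle(netd), 1e-8)   # closed forms stay exact
  }
})

test_that("minor evaluation: conventions and recurrence vs dense determinant", {
  expect_equal(minor_eval(minor_evaluator(matrix(-3, 1, 1), 1, 1), 0.7),
               1 + 0i)
  K2 <- matrix(c(-2, 1, 1, -2), 2)
  expect_equal(minor_eval(minor_evaluator(K2, 1, 1), 0.5), 0.5 + 2 + 0i)

  set.seed(507)
  inn <- inner_rate_matrix(random_chain(7))
  K <- inn$matrix
  m <- nrow(K)
  for (s in c(0.7, -1.3, 2 + 0.5i)) {
    dense11 <- delaychain:::cdet((diag(m) * s - K)[-1, -1])
    expect_equal(minor_eval(minor_evaluator(K, 1, 1), s), dense11,
                 tolerance = 1e-10)
    densemm <- delaychain:::cdet((diag(m) * s - K)[-m, -m])
    expect_equal(minor_eval(minor_evaluator(K, m, m), s), densemm,
                 tolerance = 1e-10)
  }
})

test_that("numeric first-passage oracle reproduces scalar closed forms", {
  net <- chain3(1, 2)
  gen <- build_generator(net, absorbing = c("S1", "S3"))
  tt <- seq(0.01, 4, length.out = 60)
  tab <- numeric_first_passage_cdf(gen, "S2", c("S1", "S3"), grid = tt)
  pr <- attr(tab, "probabilities")
  expect_equal(unname(pr[["S3"]]), 1 / 3, tolerance = 1e-9)
  # unconditional absorbed mass at S3: (1/3)(1 - e^{-3t})
  expect_equal(tab$S3 * pr[["S3"]], (1 / 3) * (1 - exp(-3 * tt)),
               tolerance = 1e-9)

  tab4 <- numeric_first_passage_cdf(
    build_generator(chain4_sym(), absorbing = c("S1", "S4")),
    "S2", c("S1", "S4"))
  pr4 <- attr(tab4, "probabilities")
  expect_equal(unname(pr4), c(2 / 3, 1 / 3), tolerance = 1e-9)

  expect_error(numeric_first_passage_cdf(
    build_generator(chain4_sym(), absorbing = "S1"), "S2", c("S1", "S4")),
    "absorbing")
})

test_that("quantiles, means and u = 1 contract", {
  d <- delay_stages(c(1, 3))
  expect_equal(distribution_mean(d), 4 / 3)
  expect_equal(distribution_quantile(d, 0), 0)
  expect_error(distribution_quantile(d, 1), "unbounded")
  d1 <- delay_stages(3)
  expect_equal(distribution_quantile(d1, 0.5), log(2) / 3, tolerance = 1e-9)
  # quantile inverts the CDF for all three representations
  inn <- inner_rate_matrix(example_chain())
  for (dd in list(d, first_return_distribution(inn, "s1"),
                  delaychain:::tabulated_distribution(
                    inn, 1L, delaychain:::channel_beta(inn, "S0"),
                    arrival_return_probabilities(inn)$p_r_1))) {
    for (u in c(0.05, 0.5, 0.95)) {
      expect_equal(distribution_cdf(dd, distribution_quantile(dd, u)), u,
                   tolerance = 1e-6)
    }
  }
})

test_that("general start states agree between residue and numeric paths", {
  set.seed(508)
  net <- random_chain(7, n_bypass = 1L)
  inn <- inner_rate_matrix(net)
  beta <- delaychain:::channel_beta(inn, net$sois[2])
  for (a in c(2L, 4L)) {
    fpR <- delaychain:::fp_distribution(inn, a, beta)
    expect_equal(fpR$dist$rep$type, "residue")
    fpT <- delaychain:::tabulated_distribution(inn, a, beta, fpR$prob)
    expect_lt(max(abs(distribution_cdf(fpR$dist, fpT$rep$time) -
                        fpT$rep$cdf)), 1e-8)
  }
})
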