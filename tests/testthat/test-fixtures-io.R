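# Synthetic generators, the worked examples, and file round-trips.

test_that("random chains are reproducible and well-formed", {
  net <- random_chain(10, seed = 901, n_bypass = 2L)
  rep_ <- classify_reactions(net)
  counts <- table(rep_$reactions$kind)
  expect_equal(sum(counts[c("chain_forward", "chain_backward")]), 18L)
  expect_equal(sum(counts[grep("bypass", names(counts))]), 2L)

  f1 <- tempfile(); f2 <- tempfile()
  write_model(random_chain(6, seed = 902, n_bypass = 1L), f1)
  write_model(random_chain(6, seed = 902, n_bypass = 1L), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_equal(length(random_chain(2, seed = 903)$species), 2L)
  expect_error(chain_network(forward = rep(1, 4),
                             bypasses = tibble::tibble(from = 1L, to = 2L,
                                                       rate = 1)),
               "bypass endpoints")
})

test_that("glycolysis fixture: structure and the four-stage delay", {
  gl <- example_glycolysis()
  expect_equal(length(gl$abridged$inner$species), 4L)     # X1..X4 lumped
  dd <- gl$abridged$delayed
  expect_equal(nrow(dd), 1L)
  d <- dd$delay[[1]]
  expect_equal(d$rep$type, "stage_rates")
  expect_equal(d$rep$rates, c(2, 2, 2, 2))
  expect_equal(distribution_mean(d), sum(1 / c(2, 2, 2, 2)), tolerance = 1e-12)
  expect_equal(dd$probability, 1, tolerance = 1e-12)
  # the delayed PFK reaction keeps its state-dependent propensity
  expect_equal(dd$propensity[[1]]$type, "saturating")
  # unequal stage rates keep the stage-convolution form
  glr <- example_glycolysis(g = c(2, 1.5, 2.5, 2))
  dr <- glr$abridged$delayed$delay[[1]]
  expect_equal(sort(dr$rep$rates), sort(c(2, 1.5, 2.5, 2)))
})

test_that("proofreading fixture: completion probability and stage delays", {
  pr <- example_proofreading()
  p_closed <- (5 / (5 + 0.25))^6
  expect_lt(abs(pr$p - p_closed), 1e-10)
  dd <- pr$abridged$delayed
  expect_equal(nrow(dd), 2L)
  arr <- dd[dd$label == "first_arrival", ]
  expect_lt(abs(arr$rate - p_closed * 1), 1e-10)
  expect_equal(arr$delay[[1]]$rep$type, "stage_rates")
  expect_equal(arr$delay[[1]]$rep$rates, rep(5.25, 6))
  ret <- dd[dd$label == "first_return", ]
  expect_lt(abs(ret$rate - (1 - p_closed)), 1e-10)
  expect_equal(ret$product, "T + M")

  # tau_1 vs the matrix-exponential oracle, sup-norm < 1e-8
  inn <- pr$abridged$inner
  beta <- delaychain:::channel_beta(inn, "C6")
  tab <- delaychain:::tabulated_distribution(inn, 1L, beta, p_closed)
  expect_lt(max(abs(distribution_cdf(arr$delay[[1]], tab$rep$time) -
                      tab$rep$cdf)), 1e-8)
})

test_that("model files round-trip and report malformed input", {
  pr <- example_proofreading()
  f <- tempfile(fileext = ".yaml")
  write_model(pr$full, f)
  back <- read_model(f)
  expect_equal(back$species, pr$full$species)
  expect_equal(tidy(back)[c("reactant", "product", "rate")],
               tidy(pr$full)[c("reactant", "product", "rate")])
  expect_equal(back$initial_state, pr$full$initial_state)

  bad <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(species = list("A", "B"),
                                reactions = list(list(reactant = "A",
                                                      product = "B")))), bad)
  expect_error(read_model(bad), "missing `rate`")
})

test_that("trajectory and distribution TSVs follow the declared layout", {
  net <- reaction_network(tibble::tibble(reactant = "S1", product = "S2",
                                         rate = 2))
  set.seed(904)
  tr <- ssa_direct(net, x0 = c(S1 = 3, S2 = 0), t_end = 100,
                   record = "events")
  expect_equal(nrow(tr), 4L)                       # initial + 3 events
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(names(tab), c("time", "S1", "S2"))
  expect_equal(nrow(tab), 4L)

  d <- delay_stages(c(1, 3))
  fd <- tempfile(fileext = ".tsv")
  write_distribution(d, fd)
  expect_match(readLines(fd, n = 1L), "delay_distribution")
  d2 <- read_distribution(fd)
  tt <- seq(0, 5, length.out = 50)
  expect_lt(max(abs(distribution_cdf(d2, tt) - distribution_cdf(d, tt))),
            1e-3)

  # abridged-model serialization carries the delay descriptors
  ab <- abridge(chain3(1, 2))
  fa <- tempfile(fileext = ".yaml")
  write_abridged_model(ab, fa)
  cfg <- yaml::yaml.load_file(fa)
  expect_equal(length(cfg$delayed_reactions), 4L)
  expect_equal(cfg$delayed_reactions[[1]]$delay$type, "stage_rates")
})

test_that("the command-line interface runs end to end", {
  cli <- system.file("cli", "delaychain.R", package = "delaychain")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- tempfile(fileext = ".tsv")
  mod <- tempfile(fileext = ".yaml")
  write_model(chain3(1, 2), mod)
  status <- system2(rscript, c(cli, "dist", "--model", mod, "--out", out),
                    stdout = NULL, stderr = NULL)
  expect_equal(status, 0L)
  tab <- read.table(out, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(max(abs(tab$first_arrival_to_Sn -
                         (1 - exp(-3 * tab$time)))), 0, tolerance = 1e-9)
  status2 <- system2(rscript, c(cli, "nonsense"), stdout = NULL,
                     stderr = NULL)
  expect_false(status2 == 0L)
})
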