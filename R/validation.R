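# Brute-force oracles and statistical machinery: single-walker first-passage
# sampling, KS comparison against closed-form delays, and ensemble
# comparison (mean z-scores + terminal chi-square).

#' Sample single-walker first-passage events by direct simulation
#'
#' Runs `n_walkers` independent continuous-time jump chains (one molecule
#' moving over the unimolecular reactions of the network) from `start` until
#' a species in `stop_set` is hit or the walker degrades. This is the
#' model-free stochastic oracle for every closed-form probability and delay
#' distribution.
#'
#' @param network a [reaction_network()].
#' @param start starting species (not in `stop_set`).
#' @param stop_set absorbing species.
#' @param n_walkers number of walkers.
#' @return A tibble with `outcome` (the species hit, or `"degradation"`)
#'   and `time`, one row per walker.
#' @export
walker_first_passage_sample <- function(network, start, stop_set, n_walkers) {
  stopifnot(inherits(network, "reaction_network"), !(start %in% stop_set))
  gen <- build_generator(network, absorbing = stop_set, lump_degradation = TRUE)
  K <- gen$matrix
  sp <- colnames(K)
  stops <- c(stop_set, "*deg*")
  transient <- setdiff(sp, stops)
  if (any(-diag(K)[transient] <= 0)) {
    abort("walker cannot reach any stop state: transient state without outflow")
  }
  # mass-leak check: every transient state must reach absorption
  Q <- K[transient, transient, drop = FALSE]
  tryCatch(solve(-Q), error = function(e) {
    abort("walker cannot reach any stop state from some transient state")
  })

  n_states <- length(sp)
  rate_tot <- -diag(K)
  targets <- lapply(seq_len(n_states), function(j) {
    w <- K[, j]; w[j] <- 0
    idx <- which(w > 0)
    list(idx = idx, p = w[idx] / sum(w[idx]))
  })
  start_idx <- match(start, sp)
  stop_idx <- match(stops, sp)

  state <- rep.int(start_idx, n_walkers)
  time <- numeric(n_walkers)
  done <- logical(n_walkers)
  outcome <- integer(n_walkers)
  while (!all(done)) {
    act <- which(!done)
    for (s in unique(state[act])) {
      w <- act[state[act] == s]
      time[w] <- time[w] + rexp(length(w), rate_tot[s])
      tg <- targets[[s]]
      nxt <- if (length(tg$idx) == 1L) rep.int(tg$idx, length(w))
        else tg$idx[sample.int(length(tg$idx), length(w), replace = TRUE,
                               prob = tg$p)]
      state[w] <- nxt
      hit <- nxt %in% stop_idx
      done[w[hit]] <- TRUE
      outcome[w[hit]] <- nxt[hit]
    }
  }
  out <- tibble::tibble(
    outcome = ifelse(sp[outcome] == "*deg*", "degradation", sp[outcome]),
    time = time
  )
  attr(out, "start") <- start
  attr(out, "n_walkers") <- n_walkers
  out
}

#' One-sample Kolmogorov-Smirnov comparison against a delay distribution
#'
#' @param sample_times positive event times.
#' @param d a `delay_distribution`.
#' @param alpha significance level.
#' @return list with `statistic`, `p_value`, `pass`.
#' @export
ks_compare <- function(sample_times, d, alpha = 0.01) {
  stopifnot(length(sample_times) > 0L, inherits(d, "delay_distribution"))
  kt <- suppressWarnings(
    ks.test(sample_times, function(q) distribution_cdf(d, pmax(q, 0)))
  )
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       pass = kt$p.value > alpha)
}

#' Compare two trajectory ensembles
#'
#' Mean-difference z-scores with combined standard errors at every
#' checkpoint, and a two-sample chi-square on the pooled-binned terminal
#' histograms (adjacent bins merged until all expected counts are at least
#' 5). The two ensembles must share the recording grid.
#'
#' @param ensA,ensB `ensemble` objects from [simulate_ensemble()].
#' @param species species to compare (default: those common to both).
#' @param checkpoints subset of grid times (default: all).
#' @param alpha significance level for the terminal chi-square.
#' @return An `ensemble_comparison`: per-checkpoint tibble plus per-species
#'   chi-square results and overall pass flags in attributes.
#' @export
compare_ensembles <- function(ensA, ensB, species = NULL, checkpoints = NULL,
                              alpha = 0.01) {
  stopifnot(inherits(ensA, "ensemble"), inherits(ensB, "ensemble"))
  if (ensA$n < 2L || ensB$n < 2L) abort("need at least 2 runs per ensemble")
  if (is.null(species)) species <- intersect(ensA$species, ensB$species)
  if (is.null(checkpoints)) checkpoints <- ensA$grid
  ia <- match(checkpoints, ensA$grid)
  ib <- match(checkpoints, ensB$grid)
  if (anyNA(ia) || anyNA(ib)) abort("ensembles must share the checkpoint grid")

  rows <- list()
  for (s in species) {
    mA <- ensA$mean[ia, s]; mB <- ensB$mean[ib, s]
    se <- sqrt(ensA$var[ia, s] / ensA$n + ensB$var[ib, s] / ensB$n)
    z <- ifelse(se > 0, (mA - mB) / se, ifelse(mA == mB, 0, Inf))
    rows[[s]] <- tibble::tibble(species = s, time = checkpoints,
                                mean_a = mA, mean_b = mB, se = se, z = z)
  }
  tab <- dplyr::bind_rows(rows)

  chisq <- dplyr::bind_rows(lapply(species, function(s) {
    a <- ensA$terminal[, s]; b <- ensB$terminal[, s]
    br <- chi_bins(a, b)
    if (length(br$breaks) < 3L) {
      return(tibble::tibble(species = s, statistic = 0, df = 0, p_value = 1))
    }
    ca <- tabulate(findInterval(a, br$breaks, rightmost.closed = TRUE),
                   nbins = length(br$breaks) - 1L)
    cb <- tabulate(findInterval(b, br$breaks, rightmost.closed = TRUE),
                   nbins = length(br$breaks) - 1L)
    ct <- suppressWarnings(chisq.test(rbind(ca, cb)))
    tibble::tibble(species = s, statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p_value = ct$p.value)
  }))

  structure(tab,
            chisq = chisq,
            pass_means = all(abs(tab$z) < 3),
            pass_chisq = all(chisq$p_value > alpha),
            max_abs_z = max(abs(tab$z)),
            class = c("ensemble_comparison", class(tab)))
}

# adjacent-merge binning so that pooled expected counts are >= 5 per bin
chi_bins <- function(a, b, min_expected = 5) {
  pool <- c(a, b)
  v <- sort(unique(pool))
  if (length(v) < 2L) return(list(breaks = c(v - 0.5, v + 0.5)))
  breaks <- c(v[1] - 0.5, v + 0.5)
  repeat {
    cnt <- tabulate(findInterval(pool, breaks, rightmost.closed = TRUE),
                    nbins = length(breaks) - 1L)
    expect <- cnt / 2                      # balanced two-sample design
    if (all(expect >= min_expected) || length(breaks) <= 3L) break
    i <- which.min(expect)
    drop <- if (i == length(expect)) i else i + 1L
    breaks <- breaks[-drop]
  }
  list(breaks = breaks)
}

#' @export
print.ensemble_comparison <- function(x, ...) {
  cat("<ensemble_comparison> max |z| =", signif(attr(x, "max_abs_z"), 4),
      "-> means", if (attr(x, "pass_means")) "agree" else "DIFFER", "\n")
  ch <- attr(x, "chisq")
  for (i in seq_len(nrow(ch))) {
    cat(sprintf("  terminal chi-square %s: p = %.4g\n",
                ch$species[i], ch$p_value[i]))
  }
  invisible(x)
}

#' @export
glance.ensemble_comparison <- function(x, ...) {
  tibble::tibble(
    max_abs_z = attr(x, "max_abs_z"),
    min_chisq_p = min(attr(x, "chisq")$p_value),
    pass_means = attr(x, "pass_means"),
    pass_chisq = attr(x, "pass_chisq")
  )
}
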