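# Synthetic chain generation and the worked example systems.

#' Build a bi-directional chain network from explicit rates
#'
#' @param forward rates of \eqn{S_i \to S_{i+1}} (length `n - 1`; zeros drop
#'   the reaction).
#' @param backward rates of \eqn{S_{i+1} \to S_i} (length `n - 1`, default
#'   none).
#' @param species species names (default `S1 ... Sn`).
#' @param sois species of interest (default: the two chain ends).
#' @param bypasses data frame with columns `from`, `to` (1-based positions,
#'   `|from - to| > 1`) and `rate`.
#' @param degradations,syntheses named rates (names are species).
#' @param initial_state named counts.
#' @return A [reaction_network()].
#' @export
chain_network <- function(forward, backward = NULL, species = NULL,
                          sois = NULL, bypasses = NULL,
                          degradations = NULL, syntheses = NULL,
                          initial_state = NULL) {
  n <- length(forward) + 1L
  if (is.null(species)) species <- paste0("S", seq_len(n))
  stopifnot(length(species) == n)
  if (is.null(backward)) backward <- numeric(n - 1L)
  stopifnot(length(backward) == n - 1L)
  if (is.null(sois)) sois <- species[c(1L, n)]
  rows <- list()
  add <- function(r, p, rate) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(reactant = r, product = p,
                                                 rate = rate)
  }
  for (i in seq_len(n - 1L)) {
    if (forward[i] > 0) add(species[i], species[i + 1L], forward[i])
    if (backward[i] > 0) add(species[i + 1L], species[i], backward[i])
  }
  if (!is.null(bypasses) && nrow(bypasses)) {
    for (i in seq_len(nrow(bypasses))) {
      f <- bypasses$from[i]; t <- bypasses$to[i]
      if (f < 1 || f > n || t < 1 || t > n || abs(f - t) <= 1) {
        abort(paste0("invalid bypass endpoints (", f, ", ", t, ")"))
      }
      add(species[f], species[t], bypasses$rate[i])
    }
  }
  for (s in names(degradations)) add(s, "", degradations[[s]])
  for (s in names(syntheses)) add("", s, syntheses[[s]])
  reaction_network(dplyr::bind_rows(rows), species = species, sois = sois,
                   initial_state = initial_state)
}

#' Generate a seeded random bi-directional chain
#'
#' Rates are drawn uniformly from `rate_range`; optional bypasses connect
#' random non-adjacent intermediates (never an SOI), and optional
#' degradations/syntheses attach to random intermediates. The same seed
#' reproduces the same network exactly.
#'
#' @param n chain length (`n >= 2`).
#' @param seed RNG seed (uses the global RNG when `NULL`).
#' @param rate_range range for uniform rate draws.
#' @param n_bypass number of bypass reactions (needs `n >= 5`).
#' @param n_degradation,n_synthesis number of intermediate degradation /
#'   synthesis reactions.
#' @param unidirectional drop all backward reactions?
#' @return A [reaction_network()].
#' @export
random_chain <- function(n, seed = NULL, rate_range = c(0.5, 5),
                         n_bypass = 0L, n_degradation = 0L, n_synthesis = 0L,
                         unidirectional = FALSE) {
  stopifnot(n >= 2L)
  if (!is.null(seed)) set.seed(seed)
  ru <- function(k) runif(k, rate_range[1], rate_range[2])
  forward <- ru(n - 1L)
  backward <- if (unidirectional) numeric(n - 1L) else ru(n - 1L)
  bypasses <- NULL
  if (n_bypass > 0L) {
    if (n < 5L) abort("bypasses among intermediates need n >= 5")
    pairs <- list()
    guard <- 0L
    while (length(pairs) < n_bypass && guard < 1000L) {
      ft <- sort(sample(2:(n - 1L), 2L))
      if (diff(ft) > 1L) {
        if (runif(1) < 0.5) ft <- rev(ft)
        pairs[[length(pairs) + 1L]] <- ft
      }
      guard <- guard + 1L
    }
    bypasses <- tibble::tibble(
      from = vapply(pairs, `[`, integer(1), 1L),
      to = vapply(pairs, `[`, integer(1), 2L),
      rate = ru(length(pairs))
    )
  }
  species <- paste0("S", seq_len(n))
  degr <- synt <- NULL
  if (n_degradation > 0L && n > 2L) {
    who <- sample(2:(n - 1L), min(n_degradation, n - 2L))
    degr <- setNames(ru(length(who)), species[who])
  }
  if (n_synthesis > 0L && n > 2L) {
    who <- sample(2:(n - 1L), min(n_synthesis, n - 2L))
    synt <- setNames(ru(length(who)), species[who])
  }
  chain_network(forward, backward, species = species, bypasses = bypasses,
                degradations = degr, syntheses = synt)
}

#' Worked example: bi-directional 10-species chain with two bypasses
#'
#' A fully bi-directional chain \eqn{S_0 \ldots S_9} between the SOIs
#' \eqn{S_0} and \eqn{S_9} plus two uni-directional bypass reactions
#' (\eqn{S_2 \to S_6}, \eqn{S_7 \to S_3}). The rates are synthetic,
#' documented package defaults (forward 1.0, backward 0.7, bypasses 0.5);
#' initial condition \eqn{S_9 = 200}, everything else 0.
#'
#' @param forward,backward,bypass_rate rate overrides.
#' @param s9_0 initial count of \eqn{S_9}.
#' @return A [reaction_network()] with SOIs \eqn{S_0, S_9}.
#' @export
example_chain <- function(forward = 1, backward = 0.7, bypass_rate = 0.5,
                          s9_0 = 200) {
  species <- paste0("S", 0:9)
  chain_network(
    forward = rep(forward, 9), backward = rep(backward, 9),
    species = species, sois = c("S0", "S9"),
    bypasses = tibble::tibble(from = c(3L, 8L), to = c(7L, 4L),
                              rate = bypass_rate),
    initial_state = c(S9 = s9_0)
  )
}

#' Worked example: minimalist stochastic glycolysis
#'
#' A minimal autocatalytic glycolysis model in ATP copy number `Y`: the
#' (implicit) PFK step consumes `q` ATP with the saturating, ATP-inhibited
#' propensity \eqn{a(Y) = V (\phi Y)^q / (1 + (\phi Y)^h)}, feeding a
#' uni-directional chain of intermediates \eqn{X_1 \ldots X_4} with stage
#' rates \eqn{g_1 \ldots g_4}; the completion step releases the pathway's
#' ATP yield \eqn{m = 1 + \sum h_i} at once, basal synthesis produces ATP at
#' rate `g_y`, and ATP is consumed nonspecifically at per-molecule rate
#' `gamma`. Abridging for the single SOI `Y` lumps the chain into one
#' consuming delayed reaction \eqn{qY \to mY} whose delay is the four-stage
#' exponential convolution with the `g` rates.
#'
#' @param V,phi,q,h PFK propensity parameters.
#' @param gamma ATP consumption rate.
#' @param g chain stage rates (length 4).
#' @param g_y basal ATP synthesis rate.
#' @param h_i payoff-step ATP stoichiometries (length 3), released at
#'   completion.
#' @param Y0 initial ATP count.
#' @return list with `full` ([reaction_network()]) and `abridged`
#'   (`abridged_model`).
#' @export
example_glycolysis <- function(V = 500, phi = 0.5, q = 2, h = 5, gamma = 2,
                               g = c(2, 2, 2, 2), g_y = 0.5,
                               h_i = c(1, 1, 1), Y0 = 100) {
  stopifnot(length(g) == 4L, all(g > 0), length(h_i) == 3L)
  m_yield <- 1 + sum(h_i)
  species <- c("X1", "X2", "X3", "X4", "Y")
  rx <- tibble::tibble(
    reactant = c(paste0(q, " Y"), "X1", "X2", "X3", "X4", "", "Y"),
    product  = c("X1", "X2", "X3", "X4", paste0(m_yield, " Y"), "Y", ""),
    rate     = c(V, g, g_y, gamma)
  )
  rx$propensity <- c(list(propensity_saturating("Y", V, phi, q, h)),
                     rep(list(NULL), 6))
  full <- reaction_network(rx, species = species, sois = "Y",
                           initial_state = c(Y = Y0))
  list(full = full, abridged = abridge(full))
}

#' Worked example: kinetic proofreading in T-cell receptor signalling
#'
#' Receptor `T` and peptide `M` bind (rate `k1`) into a nascent complex
#' `C0` that undergoes `N` modification steps (rate `kp` each), any of
#' which can instead dissociate back to `T + M` (rate `k_minus1`), before
#' the fully active complex `C_N` is formed. The abridged model keeps the
#' SOIs `T`, `M` and `C_N`: binding fires at rate `p k1 T M` into a delayed
#' production of `C_N` (delay: the `N`-fold convolution of
#' `Exp(kp + k_minus1)` stages) and at rate `(1 - p) k1 T M` into a delayed
#' regeneration of `T + M`, where `p = (kp / (kp + k_minus1))^N` is the
#' completion probability.
#'
#' @param k1,k_minus1,kp binding, dissociation and modification rates.
#' @param N number of intermediate steps.
#' @param T0,M0 initial receptor / peptide counts.
#' @return list with `full`, `abridged` and the completion probability `p`.
#' @export
example_proofreading <- function(k1 = 1, k_minus1 = 0.25, kp = 5, N = 6L,
                                 T0 = 200, M0 = 200) {
  stopifnot(N >= 1L, k1 > 0, k_minus1 > 0, kp > 0)
  cn <- paste0("C", 0:N)
  species <- c("T", "M", cn)
  rows <- list(tibble::tibble(reactant = "T + M", product = "C0", rate = k1))
  for (i in seq_len(N)) {
    rows[[length(rows) + 1L]] <-
      tibble::tibble(reactant = cn[i], product = cn[i + 1L], rate = kp)
    rows[[length(rows) + 1L]] <-
      tibble::tibble(reactant = cn[i], product = "T + M", rate = k_minus1)
  }
  full <- reaction_network(dplyr::bind_rows(rows), species = species,
                           sois = c("T", "M", cn[N + 1L]),
                           initial_state = c(T = T0, M = M0))
  abridged <- abridge(full)
  list(full = full, abridged = abridged,
       p = (kp / (kp + k_minus1))^N)
}
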