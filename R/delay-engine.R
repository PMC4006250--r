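# First-arrival and first-return time distributions and event probabilities:
# closed forms (stage convolution / eigenvalue residues with minor-based
# coefficients) where available, matrix-exponential tabulation as the
# documented numeric fallback and as the independent oracle.

# ---- matrix exponential action by uniformization ---------------------------
# p(t) = exp(A t) v for a (sub)generator A in column convention, computed by
# the randomization series with Poisson weights; truncation error < tol.
expm_vec <- function(A, v, t, tol = 1e-14) {
  if (t == 0) return(v)
  m <- nrow(A)
  L <- max(-diag(A), 0) * 1.0000001 + 1e-300
  n_sub <- max(1L, ceiling(L * t / 200))
  dt <- t / n_sub
  mu <- L * dt
  P <- diag(m) + A / L
  for (s in seq_len(n_sub)) {
    w <- exp(-mu)
    term <- v
    acc <- w * term
    k <- 1L
    kmax <- ceiling(mu + 8 * sqrt(mu + 1) + 25)
    while (k <= kmax) {
      term <- P %*% term
      w <- w * mu / k
      acc <- acc + w * term
      if (w < tol && k > mu) break
      k <- k + 1L
    }
    v <- as.numeric(acc)
  }
  v
}

# ---- eigenvalues -----------------------------------------------------------

#' Eigenvalues of the inner rate matrix
#'
#' Returns the eigenvalues \eqn{\lambda_k} of the inner rate matrix (all with
#' negative real part for a dissipative block; anything else is an error) and
#' a simplicity flag: eigenvalues closer than `rel_tol` times the spectral
#' radius are treated as non-simple, because the residue closed forms assume
#' simple poles and become numerically unstable near degeneracy.
#'
#' @param K an `inner_rate_matrix` or plain square matrix.
#' @param rel_tol relative gap below which eigenvalues count as coincident.
#' @return list with `values` (complex), `simple` (flag), `real` (flag).
#' @export
eigvals_inner <- function(K, rel_tol = 1e-8) {
  M <- if (inherits(K, "inner_rate_matrix")) K$matrix else K
  if (nrow(M) == 0L) abort("no intermediates: empty inner matrix")
  if (any(!is.finite(M))) abort("inner matrix must be finite")
  lam <- eigen(M, only.values = TRUE)$values
  rad <- max(Mod(lam))
  if (any(Re(lam) >= -rad * 1e-12)) {
    abort("not a dissipative inner system: eigenvalue with nonnegative real part")
  }
  simple <- TRUE
  if (length(lam) > 1L) {
    d <- abs(outer(lam, lam, "-"))
    simple <- min(d[upper.tri(d)]) >= rel_tol * rad
  }
  list(values = lam, simple = simple,
       real = all(abs(Im(lam)) <= 1e-9 * rad))
}

# ---- probabilities ---------------------------------------------------------

# absorption probabilities from one start state: named vector over channels
# plus "deg"; exact linear solve  beta' (-K)^{-1} e_start.
absorb_probs <- function(inner, start) {
  m <- length(inner$species)
  Kt <- -inner$matrix
  e <- numeric(m); e[start] <- 1
  x <- tryCatch(solve(Kt, e), error = function(e2) {
    abort("walker cannot reach any stop state (singular inner matrix)")
  })
  probs <- vapply(inner$channels, function(ch) sum(ch$beta * x), numeric(1))
  c(probs, deg = sum(inner$deg * x))
}

#' Arrival, return and degradation probabilities of the lumped block
#'
#' For the two-boundary-SOI chain: \eqn{p_{r,1}} is the probability that a
#' walker starting at \eqn{S_2} returns to \eqn{S_1} without visiting
#' \eqn{S_n}; \eqn{p_{a,n} } that it arrives at \eqn{S_n} first;
#' \eqn{p_{deg,1}} that it degrades en route (and symmetrically from
#' \eqn{S_{n-1}}). Computed by the exact absorption solve; the identities
#' \eqn{p_{r,1} + p_{a,n} + p_{deg,1} = 1} hold to machine precision.
#'
#' @param inner an `inner_rate_matrix` from [inner_rate_matrix()].
#' @return A `passage_probabilities` object (also a one-row tibble).
#' @export
arrival_return_probabilities <- function(inner) {
  stopifnot(inherits(inner, "inner_rate_matrix"))
  if (no_intermediates(inner)) abort("no intermediates")
  m <- length(inner$species)
  s1 <- inner$absorbing[1]; sn <- inner$absorbing[2]
  from2 <- absorb_probs(inner, 1L)
  fromn1 <- absorb_probs(inner, m)
  pick <- function(pr, soi) {
    idx <- vapply(inner$channels, function(ch) identical(ch$target, soi), logical(1))
    sum(pr[which(idx)])
  }
  out <- tibble::tibble(
    p_r_1 = pick(from2, s1), p_a_n = pick(from2, sn),
    p_deg_1 = unname(from2["deg"]),
    p_r_n = pick(fromn1, sn), p_a_1 = pick(fromn1, s1),
    p_deg_n = unname(fromn1["deg"])
  )
  class(out) <- c("passage_probabilities", class(out))
  out
}

# ---- closed-form / fallback first-passage distributions --------------------

# Residue form for the conditional density of absorption through channel
# `beta` starting at block index `a`:
#   f(t) = sum_k w_k e^{lambda_k t},
#   w_k  = sum_i beta_i (-1)^{a+i} M_{a,i}(lambda_k) / prod_{j!=k}(lambda_k - lambda_j),
# where M_{a,i}(s) is the (a,i)-minor of (sI - K). The CDF coefficients are
# c_k = -w_k / (lambda_k p) with p the channel probability, so that
# F(t) = 1 - sum_k c_k e^{lambda_k t}.
residue_distribution <- function(inner, a, beta, prob, lam, label = NULL) {
  K <- inner$matrix
  m <- nrow(K)
  nz <- which(beta != 0)
  w <- vapply(seq_along(lam), function(k) {
    dk <- prod(lam[k] - lam[-k])
    s <- 0 + 0i
    for (i in nz) {
      ev <- minor_evaluator(K, a, i)
      s <- s + beta[i] * (-1)^(a + i) * minor_eval(ev, lam[k])
    }
    s / dk
  }, complex(1))
  coef <- -w / (lam * prob)
  if (abs(sum(coef) - 1) > 1e-7) return(NULL)   # numerically unusable
  d <- delay_residues(lam, coef, label = label)
  # proper-CDF sanity on a coarse grid; fall back rather than be silently wrong
  tchk <- distribution_scale(d) * c(0.05, 0.2, 0.5, 1, 2, 5, 20)
  Fv <- distribution_cdf(d, tchk)
  if (any(diff(c(0, Fv)) < -1e-9) || abs(Fv[length(Fv)] - 1) > 1e-6) return(NULL)
  d
}

# numeric tabulation of the conditional CDF for one channel (the documented
# fallback representation when no closed form applies)
tabulated_distribution <- function(inner, a, beta, prob, label = NULL,
                                   tail_tol = 1e-9, n_grid = 512L,
                                   max_refine = 2L) {
  K <- inner$matrix
  m <- nrow(K)
  A <- rbind(cbind(K, 0), c(beta, 0))       # channel-absorbed mass as state m+1
  v0 <- c(as.numeric(seq_len(m) == a), 0)
  rate_max <- max(-diag(K))
  t_lo <- 0.01 / rate_max
  t_hi <- 10 / min(abs(Re(eigen(K, only.values = TRUE)$values)))
  transient <- function(t) sum(expm_vec(A, v0, t)[seq_len(m)])
  while (transient(t_hi) > tail_tol) t_hi <- t_hi * 2
  build <- function(n) {
    tt <- c(0, exp(seq(log(t_lo), log(t_hi), length.out = n)))
    Fv <- numeric(length(tt))
    v <- v0
    for (i in seq_along(tt)[-1]) {
      v <- expm_vec(A, v, tt[i] - tt[i - 1])
      Fv[i] <- v[m + 1]
    }
    list(time = tt, cdf = Fv / prob)
  }
  g <- build(n_grid)
  for (r in seq_len(max_refine)) {
    g2 <- build(n_grid * 2L^r)
    interp <- approx(g$time, g$cdf, xout = g2$time, rule = 2)$y
    g <- g2
    if (max(abs(interp - g2$cdf)) < 1e-9) break
  }
  delay_tabulated(g$time, pmin(g$cdf, 1), label = label, fallback = TRUE)
}

# Representation chooser for absorption through `beta` starting at index `a`.
fp_distribution <- function(inner, a, beta, label = NULL) {
  K <- inner$matrix
  m <- nrow(K)
  prob <- sum(beta * solve(-K, as.numeric(seq_len(m) == a)))
  if (prob <= 0) return(list(prob = 0, dist = NULL))

  sub_only <- m == 1L || all(K[col(K) > row(K)] == 0)
  sup_only <- m == 1L || all(K[col(K) < row(K)] == 0)
  lower_bidiag <- sub_only && all(K[row(K) - col(K) > 1L] == 0)
  upper_bidiag <- sup_only && all(K[col(K) - row(K) > 1L] == 0)

  # uni-directional flow with a single terminal exit: the walk visits each
  # stage once, so the conditional law is the stage convolution of the total
  # outflow rates -- valid for any eigenvalue multiplicity
  if (lower_bidiag && all(beta[-m] == 0) && beta[m] > 0 && a <= m) {
    return(list(prob = prob,
                dist = delay_stages(-diag(K)[a:m], label = label)))
  }
  if (upper_bidiag && all(beta[-1] == 0) && beta[1] > 0 && a >= 1) {
    return(list(prob = prob,
                dist = delay_stages(-diag(K)[a:1], label = label)))
  }

  ei <- eigvals_inner(inner)
  lam <- ei$values

  # tridiagonal end-to-end arrival: the stage convolution with rates
  # |lambda_k|, identical for both directions
  tri <- isTRUE(inner$tridiagonal)
  if (tri && ei$real &&
      ((a == 1L && all(beta[-m] == 0) && beta[m] > 0) ||
       (a == m && all(beta[-1] == 0) && beta[1] > 0))) {
    return(list(prob = prob, dist = delay_stages(sort(abs(Re(lam))),
                                                 label = label)))
  }

  if (ei$simple) {
    d <- residue_distribution(inner, a, beta, prob, lam, label = label)
    if (!is.null(d)) return(list(prob = prob, dist = d))
  }
  list(prob = prob,
       dist = tabulated_distribution(inner, a, beta, prob, label = label))
}

channel_beta <- function(inner, soi) {
  b <- setNames(numeric(length(inner$species)), inner$species)
  for (ch in inner$channels) if (identical(ch$target, soi)) b <- b + ch$beta
  b
}

#' First-arrival time distribution between the two boundary SOIs
#'
#' Conditional law of the time a walker leaving one SOI takes to reach the
#' other SOI without revisiting its origin. For a plain tridiagonal chain
#' this is the convolution of exponentials with the eigenvalue magnitudes
#' \eqn{|\lambda_k|} of the inner rate matrix -- identical for both
#' directions. With bypass reactions the two directions differ and the
#' direction-specific eigenvalue/residue form is used (complex-conjugate
#' eigenvalue pairs are combined into real damped-cosine terms); when the
#' eigenvalues are not simple the documented numeric tabulation is returned
#' and flagged.
#'
#' @param inner an `inner_rate_matrix`.
#' @param direction `"toward_sn"` (start \eqn{S_2}) or `"toward_s1"`
#'   (start \eqn{S_{n-1}}).
#' @return A `delay_distribution`.
#' @export
first_arrival_distribution <- function(inner,
                                       direction = c("toward_sn", "toward_s1")) {
  stopifnot(inherits(inner, "inner_rate_matrix"))
  direction <- match.arg(direction)
  if (no_intermediates(inner)) abort("no intermediates")
  m <- length(inner$species)
  if (direction == "toward_sn") {
    res <- fp_distribution(inner, 1L, channel_beta(inner, inner$absorbing[2]),
                           label = "first_arrival_to_Sn")
  } else {
    res <- fp_distribution(inner, m, channel_beta(inner, inner$absorbing[1]),
                           label = "first_arrival_to_S1")
  }
  if (is.null(res$dist)) abort("arrival probability is zero in this direction")
  res$dist
}

#' First-return time distribution at one boundary SOI
#'
#' Conditional law of the time a walker leaving \eqn{S_1} (through
#' \eqn{S_2}) takes to come back to \eqn{S_1} without visiting \eqn{S_n},
#' or symmetrically at \eqn{S_n}. Uses the eigenvalue/residue form whose
#' coefficients are the corner minors \eqn{M_{1,1}(\lambda_k)} (return to
#' \eqn{S_1}) or \eqn{M_{m,m}(\lambda_k)} (return to \eqn{S_n}) of
#' \eqn{sI - \tilde K}, evaluated by the tridiagonal recurrence when the
#' chain has no bypasses. Unlike first-arrival, the two first-return laws
#' differ in general.
#'
#' @param inner an `inner_rate_matrix`.
#' @param end `"s1"` or `"sn"`.
#' @return A `delay_distribution`.
#' @export
first_return_distribution <- function(inner, end = c("s1", "sn")) {
  stopifnot(inherits(inner, "inner_rate_matrix"))
  end <- match.arg(end)
  if (no_intermediates(inner)) abort("no intermediates")
  m <- length(inner$species)
  if (end == "s1") {
    res <- fp_distribution(inner, 1L, channel_beta(inner, inner$absorbing[1]),
                           label = "first_return_to_S1")
  } else {
    res <- fp_distribution(inner, m, channel_beta(inner, inner$absorbing[2]),
                           label = "first_return_to_Sn")
  }
  if (is.null(res$dist)) abort("return probability is zero at this end")
  res$dist
}

# ---- numeric oracle --------------------------------------------------------

#' Numeric first-passage CDFs by matrix exponentials
#'
#' The model-free oracle: propagates \eqn{p(t) = e^{Kt} e_{start}} on the
#' full generator (uniformization, truncation error below 1e-13) and reads
#' the absorbed mass at each target. Returns per-target conditional CDFs
#' (normalized by the absorption probability) on a geometric grid that is
#' auto-extended until the remaining transient mass falls below `tail_tol`.
#'
#' @param gen a `generator_matrix` whose `absorbing` set contains `targets`.
#' @param start starting species (not a target).
#' @param targets absorbing target species.
#' @param grid optional explicit time grid.
#' @param tail_tol remaining transient mass at the final grid time.
#' @param n_grid grid size when auto-generated.
#' @return An `fp_tabulation`: tibble with `time` and one conditional-CDF
#'   column per target; absorption probabilities in `attr(, "probabilities")`.
#' @export
numeric_first_passage_cdf <- function(gen, start, targets, grid = NULL,
                                      tail_tol = 1e-9, n_grid = 512L) {
  stopifnot(inherits(gen, "generator_matrix"))
  K <- gen$matrix
  sp <- colnames(K)
  if (!all(targets %in% sp)) abort("unknown target species")
  if (start %in% targets) abort("start must not be a target")
  if (any(colSums(abs(K[, targets, drop = FALSE])) > 0)) {
    abort("targets must be absorbing in the generator")
  }
  transient_states <- setdiff(sp, c(targets, "*deg*"))
  transient_states <- transient_states[diag(K)[transient_states] < 0]
  v0 <- as.numeric(sp == start)

  if (is.null(grid)) {
    rate_max <- max(-diag(K))
    t_lo <- 0.01 / rate_max
    t_hi <- 100 / rate_max
    while (sum(expm_vec(K, v0, t_hi)[match(transient_states, sp)]) > tail_tol) {
      t_hi <- t_hi * 2
    }
    grid <- c(0, exp(seq(log(t_lo), log(t_hi), length.out = n_grid)))
  }

  P <- matrix(0, length(grid), length(targets),
              dimnames = list(NULL, targets))
  v <- v0
  tprev <- 0
  for (i in seq_along(grid)) {
    v <- expm_vec(K, v, grid[i] - tprev)
    tprev <- grid[i]
    P[i, ] <- v[match(targets, sp)]
  }
  probs <- P[nrow(P), ]
  # extend for the limit (probabilities) until transient mass is negligible
  t_ext <- grid[length(grid)]
  vv <- v
  while (sum(vv[match(transient_states, sp)]) > 1e-12 && t_ext < grid[length(grid)] * 1e6) {
    vv <- expm_vec(K, vv, t_ext)
    t_ext <- 2 * t_ext
    probs <- vv[match(targets, sp)]
  }
  cond <- sweep(P, 2, pmax(probs, 1e-300), "/")
  out <- tibble::as_tibble(as.data.frame(cbind(time = grid, cond)))
  attr(out, "probabilities") <- setNames(as.numeric(probs), targets)
  class(out) <- c("fp_tabulation", class(out))
  out
}
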