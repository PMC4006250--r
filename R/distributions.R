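# Delay distributions: first-arrival / first-return laws in one of three
# representations.
#
#  * stage_rates  -- convolution of exponentials with the given stage rates
#                    (hypoexponential; valid also with repeated rates),
#  * residue      -- F(t) = 1 - sum_k  e^{a_k t} (A_k cos b_k t - B_k sin b_k t),
#                    one term per real eigenvalue, one combined term per
#                    complex-conjugate pair,
#  * tabulated    -- monotone-interpolated numeric CDF on a time grid.

new_delay_distribution <- function(rep, label = NULL, fallback = FALSE) {
  stopifnot(rep$type %in% c("stage_rates", "residue", "tabulated"))
  structure(list(rep = rep, label = label, fallback = fallback),
            class = "delay_distribution")
}

#' Delay distribution constructors
#'
#' `delay_stages()` builds the convolution of exponential stage times with
#' the given positive rates (mean `sum(1/rates)`). `delay_residues()` builds
#' the eigenvalue/residue form \eqn{F(t) = 1 - \sum_k c_k e^{\lambda_k t}}
#' from (possibly complex) eigenvalues with negative real part and
#' coefficients; conjugate pairs are combined into real damped-cosine terms.
#' `delay_tabulated()` wraps a numeric CDF tabulation.
#'
#' @param rates positive stage rates.
#' @param lambda,coef complex eigenvalues (Re < 0) and coefficients with
#'   `sum(coef)` equal to 1 (so that `F(0) = 0`).
#' @param time,cdf nondecreasing tabulation with `cdf[1]` near 0 and final
#'   value near 1.
#' @param label optional label naming the distribution.
#' @return A `delay_distribution`.
#' @export
delay_stages <- function(rates, label = NULL) {
  stopifnot(length(rates) >= 1L, all(is.finite(rates)), all(rates > 0))
  new_delay_distribution(list(type = "stage_rates", rates = as.numeric(rates)),
                         label = label)
}

#' @rdname delay_stages
#' @export
delay_residues <- function(lambda, coef, label = NULL) {
  stopifnot(length(lambda) == length(coef), all(Re(lambda) < 0))
  if (abs(sum(Re(coef)) - 1) > 1e-6 || abs(sum(Im(coef))) > 1e-6) {
    abort("residue coefficients must sum to 1 (F(0) = 0)")
  }
  terms <- combine_conjugate_terms(lambda, coef)
  new_delay_distribution(list(type = "residue", terms = terms), label = label)
}

#' @rdname delay_stages
#' @export
delay_tabulated <- function(time, cdf, label = NULL, fallback = FALSE) {
  stopifnot(length(time) == length(cdf), !is.unsorted(time))
  cdf <- cummax(pmin(pmax(cdf, 0), 1))     # enforce monotone within fp noise
  if (time[1] > 0) { time <- c(0, time); cdf <- c(0, cdf) }
  new_delay_distribution(list(type = "tabulated", time = time, cdf = cdf),
                         label = label, fallback = fallback)
}

# Pair complex-conjugate eigenvalues and emit real terms
#   c e^{l t} + Conj(c) e^{Conj(l) t} = e^{at} (A cos bt - B sin bt),
# with A = 2 Re c, B = 2 Im c; real eigenvalues give (A = Re c, B = 0).
combine_conjugate_terms <- function(lambda, coef) {
  used <- rep(FALSE, length(lambda))
  out <- NULL
  tol <- 1e-8 * max(Mod(lambda), 1)
  for (k in seq_along(lambda)) {
    if (used[k]) next
    lk <- lambda[k]
    if (abs(Im(lk)) <= tol) {
      out <- rbind(out, c(Re(lk), 0, Re(coef[k]) + 0, 0))
      used[k] <- TRUE
    } else {
      mate <- which(!used & abs(Re(lambda) - Re(lk)) <= tol &
                      abs(Im(lambda) + Im(lk)) <= tol)
      if (length(mate) == 0L) {
        abort("complex eigenvalue without conjugate mate")
      }
      mate <- mate[1]
      out <- rbind(out, c(Re(lk), abs(Im(lk)),
                          2 * Re(coef[k]),
                          2 * Im(coef[k]) * sign(Im(lk))))
      used[c(k, mate)] <- TRUE
    }
  }
  colnames(out) <- c("alpha", "beta", "A", "B")
  out
}

residue_cdf <- function(terms, t) {
  out <- numeric(length(t))
  for (r in seq_len(nrow(terms))) {
    a <- unname(terms[r, 1]); b <- unname(terms[r, 2])
    A <- unname(terms[r, 3]); B <- unname(terms[r, 4])
    out <- out + exp(a * t) * (A * cos(b * t) - B * sin(b * t))
  }
  pmin(pmax(1 - out, 0), 1)
}

residue_pdf <- function(terms, t) {
  out <- numeric(length(t))
  for (r in seq_len(nrow(terms))) {
    a <- unname(terms[r, 1]); b <- unname(terms[r, 2])
    A <- unname(terms[r, 3]); B <- unname(terms[r, 4])
    # d/dt of e^{at}(A cos bt - B sin bt)
    out <- out + exp(a * t) *
      ((a * A - b * B) * cos(b * t) - (a * B + b * A) * sin(b * t))
  }
  pmax(-out, 0)
}

# Hypoexponential CDF; exact for distinct rates, Erlang for all-equal rates,
# small phase-type matrix exponential otherwise.
hypoexp_cdf <- function(rates, t) {
  m <- length(rates)
  if (m == 1L) return(1 - exp(-rates * t))
  if (max(table(signif(rates, 12))) == 1L) {
    out <- numeric(length(t))
    for (k in seq_len(m)) {
      ck <- prod(rates[-k] / (rates[-k] - rates[k]))
      out <- out + ck * exp(-rates[k] * t)
    }
    return(pmin(pmax(1 - out, 0), 1))
  }
  if (all(abs(rates - rates[1]) < 1e-12 * rates[1])) {
    return(stats::pgamma(t, shape = m, rate = rates[1]))
  }
  # mixed multiplicities: phase-type via the bidiagonal stage generator
  Tm <- diag(-rates, m)
  if (m > 1) Tm[cbind(2:m, 1:(m - 1))] <- rates[1:(m - 1)]
  vapply(t, function(ti) {
    1 - sum(expm_vec(Tm, c(1, numeric(m - 1)), ti))
  }, numeric(1))
}

hypoexp_pdf <- function(rates, t) {
  m <- length(rates)
  if (m == 1L) return(rates * exp(-rates * t))
  if (max(table(signif(rates, 12))) == 1L) {
    out <- numeric(length(t))
    for (k in seq_len(m)) {
      ck <- prod(rates[-k] / (rates[-k] - rates[k]))
      out <- out + ck * rates[k] * exp(-rates[k] * t)
    }
    return(pmax(out, 0))
  }
  if (all(abs(rates - rates[1]) < 1e-12 * rates[1])) {
    return(stats::dgamma(t, shape = m, rate = rates[1]))
  }
  Tm <- diag(-rates, m)
  Tm[cbind(2:m, 1:(m - 1))] <- rates[1:(m - 1)]
  vapply(t, function(ti) {
    p <- expm_vec(Tm, c(1, numeric(m - 1)), ti)
    rates[m] * p[m]
  }, numeric(1))
}

#' Evaluate, invert, summarize and sample a delay distribution
#'
#' `distribution_cdf()` and `distribution_pdf()` evaluate the CDF/PDF at
#' nonnegative times; `distribution_quantile()` inverts the CDF by bracketed
#' bisection to a probability tolerance of 1e-10; `distribution_mean()` uses
#' the closed form `sum(1/rates)` for stage representations and numeric
#' integration of the survival function otherwise; `sample_delay()` draws
#' `n` variates (exact stage-wise exponential sums for the stage form,
#' inverse-CDF otherwise), consuming R's global RNG stream.
#'
#' @param d a `delay_distribution`.
#' @param t nonnegative times.
#' @param u probabilities in `[0, 1)`.
#' @param n number of draws.
#' @export
distribution_cdf <- function(d, t) {
  stopifnot(inherits(d, "delay_distribution"), all(t >= 0))
  switch(d$rep$type,
    stage_rates = hypoexp_cdf(d$rep$rates, t),
    residue = residue_cdf(d$rep$terms, t),
    tabulated = {
      out <- approx(d$rep$time, d$rep$cdf, xout = pmin(t, max(d$rep$time)),
                    rule = 2, ties = "ordered")$y
      out
    }
  )
}

#' @rdname distribution_cdf
#' @export
distribution_pdf <- function(d, t) {
  stopifnot(inherits(d, "delay_distribution"), all(t >= 0))
  switch(d$rep$type,
    stage_rates = hypoexp_pdf(d$rep$rates, t),
    residue = residue_pdf(d$rep$terms, t),
    tabulated = {
      # finite-difference slope of the monotone interpolant
      h <- diff(range(d$rep$time)) * 1e-6
      (distribution_cdf(d, t + h) - distribution_cdf(d, pmax(t - h, 0))) /
        (t + h - pmax(t - h, 0))
    }
  )
}

#' @rdname distribution_cdf
#' @export
distribution_quantile <- function(d, u) {
  stopifnot(inherits(d, "delay_distribution"))
  if (any(u >= 1)) abort("u = 1 has no finite quantile (unbounded support)")
  if (any(u < 0)) abort("u must lie in [0, 1)")
  out <- numeric(length(u))
  pos <- which(u > 0)
  if (!length(pos)) return(out)
  up <- u[pos]
  hi0 <- distribution_scale(d)
  it <- 0L
  while (distribution_cdf(d, hi0) < max(up)) {
    hi0 <- hi0 * 2
    it <- it + 1L
    if (it > 400L) abort("CDF does not reach the requested probability")
  }
  # simultaneous bracketed bisection on the (monotone) CDF
  lo <- numeric(length(up))
  hi <- rep(hi0, length(up))
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    fm <- distribution_cdf(d, mid)
    low <- fm < up
    lo[low] <- mid[low]
    hi[!low] <- mid[!low]
    if (max(abs(fm - up)) < 1e-10 && i > 40) break
  }
  out[pos] <- (lo + hi) / 2
  out
}

distribution_scale <- function(d) {
  switch(d$rep$type,
    stage_rates = sum(1 / d$rep$rates),
    residue = 1 / min(abs(d$rep$terms[, 1])),
    tabulated = max(d$rep$time) / 4
  )
}

#' @rdname distribution_cdf
#' @export
distribution_mean <- function(d) {
  stopifnot(inherits(d, "delay_distribution"))
  switch(d$rep$type,
    stage_rates = sum(1 / d$rep$rates),
    residue = {
      # E[T] = int (1 - F) dt; for F = 1 - sum e^{at}(A cos - B sin):
      # int_0^inf e^{at} cos bt dt = -a/(a^2+b^2), int e^{at} sin bt = -b/(a^2+b^2)
      tm <- d$rep$terms
      sum(tm[, 3] * (-tm[, 1]) / (tm[, 1]^2 + tm[, 2]^2) -
            tm[, 4] * (tm[, 2]) / (tm[, 1]^2 + tm[, 2]^2))
    },
    tabulated = {
      tt <- d$rep$time; FF <- d$rep$cdf
      sum(diff(tt) * (1 - (head(FF, -1) + tail(FF, -1)) / 2))
    }
  )
}

#' @rdname distribution_cdf
#' @export
sample_delay <- function(d, n = 1L) {
  stopifnot(inherits(d, "delay_distribution"))
  switch(d$rep$type,
    stage_rates = {
      draws <- vapply(d$rep$rates, function(r) rexp(n, r), numeric(n))
      if (n == 1L) sum(draws) else rowSums(matrix(draws, nrow = n))
    },
    residue = distribution_quantile(d, runif(n)),
    tabulated = {
      u <- pmin(runif(n), max(d$rep$cdf))
      approx(d$rep$cdf, d$rep$time, xout = u, rule = 2, ties = "ordered")$y
    }
  )
}

#' @export
print.delay_distribution <- function(x, ...) {
  cat("<delay_distribution",
      if (!is.null(x$label)) paste0(" '", x$label, "'"), "> ",
      x$rep$type, sep = "")
  if (x$rep$type == "stage_rates") {
    cat(" (", length(x$rep$rates), " stages)", sep = "")
  }
  if (x$rep$type == "residue") cat(" (", nrow(x$rep$terms), " terms)", sep = "")
  if (isTRUE(x$fallback)) cat(" [numeric fallback]")
  cat("\n  mean ", signif(distribution_mean(x), 6), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.delay_distribution <- function(x, ...) {
  switch(x$rep$type,
    stage_rates = tibble::tibble(term = seq_along(x$rep$rates),
                                 rate = x$rep$rates),
    residue = tibble::as_tibble(as.data.frame(x$rep$terms)),
    tabulated = tibble::tibble(time = x$rep$time, cdf = x$rep$cdf)
  )
}

#' @export
glance.delay_distribution <- function(x, ...) {
  tibble::tibble(
    representation = x$rep$type,
    mean = distribution_mean(x),
    median = distribution_quantile(x, 0.5),
    q99 = distribution_quantile(x, 0.99),
    fallback = isTRUE(x$fallback)
  )
}

#' Export a delay distribution CDF as a two-column TSV
#'
#' Writes `time` and `cdf` columns with a `#` header comment naming the
#' distribution; the grid spans the distribution up to the `1 - 1e-9`
#' quantile (or the stored grid for tabulated forms).
#'
#' @param d a `delay_distribution`.
#' @param path output file.
#' @param n_grid number of grid points for closed-form representations.
#' @export
write_distribution <- function(d, path, n_grid = 512L) {
  if (d$rep$type == "tabulated") {
    tt <- d$rep$time; FF <- d$rep$cdf
  } else {
    t_max <- distribution_quantile(d, 1 - 1e-9)
    tt <- seq(0, t_max, length.out = n_grid)
    FF <- distribution_cdf(d, tt)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# delay_distribution\t",
                    if (is.null(d$label)) "unnamed" else d$label,
                    "\t", d$rep$type), con)
  writeLines("time\tcdf", con)
  writeLines(paste(format(tt, digits = 15), format(FF, digits = 15),
                   sep = "\t"), con)
  invisible(path)
}

#' Read back a distribution TSV written by [write_distribution()]
#' @param path file path.
#' @export
read_distribution <- function(path) {
  hdr <- readLines(path, n = 1L)
  label <- strsplit(sub("^# delay_distribution\t", "", hdr), "\t")[[1]][1]
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  delay_tabulated(tab$time, tab$cdf, label = label)
}
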