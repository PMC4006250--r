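# Stochastic simulation: direct-method SSA for full models, rejection-method
# DSSA for abridged models with consuming delayed reactions.

encode_reactions <- function(species, r_stoich, p_stoich, rates, props) {
  nsp <- length(species)
  nr <- length(rates)
  react <- matrix(0L, nsp, nr)
  change <- matrix(0L, nsp, nr)
  ptype <- integer(nr)
  ppar <- vector("list", nr)
  for (j in seq_len(nr)) {
    r <- r_stoich[[j]]; p <- p_stoich[[j]]
    react[match(names(r), species), j] <- as.integer(r)
    change[, j] <- -react[, j]
    if (length(p)) {
      idx <- match(names(p), species)
      change[idx, j] <- change[idx, j] + as.integer(p)
    }
    pr <- props[[j]]
    if (is.null(pr)) {
      ptype[j] <- 0L
      ppar[[j]] <- numeric(0)
    } else if (identical(pr$type, "saturating")) {
      ptype[j] <- 1L
      ppar[[j]] <- c(pr$V, pr$phi, pr$q, pr$h,
                     match(pr$species, species) - 1,
                     if (is.null(pr$weight)) 1 else pr$weight)
    } else {
      abort(paste0("unknown propensity type '", pr$type, "'"))
    }
  }
  list(react = react, change = change, ptype = ptype, ppar = ppar)
}

make_trajectory <- function(res, species, grid, record, model_id, x0) {
  if (record == "events") {
    st <- t(res$event_states)
    colnames(st) <- species
    out <- tibble::as_tibble(as.data.frame(st))
    out <- dplyr::bind_cols(tibble::tibble(time = res$event_times), out)
  } else {
    st <- t(res$grid_state)
    colnames(st) <- species
    out <- tibble::as_tibble(as.data.frame(st))
    out <- dplyr::bind_cols(tibble::tibble(time = grid), out)
  }
  attr(out, "model_id") <- model_id
  attr(out, "final") <- setNames(as.numeric(res$final), species)
  class(out) <- c("trajectory", class(out))
  out
}

#' Direct-method stochastic simulation of a full model
#'
#' Statistically exact Gillespie direct-method trajectory under mass-action
#' propensities (unimolecular `c x`, bimolecular `c xA xB`, `c x (x-1)` for
#' identical pairs) or declared state-dependent propensities. Terminates at
#' `t_end` or when the total propensity vanishes. Consumes R's global RNG;
#' call `set.seed()` for reproducibility.
#'
#' @param network a [reaction_network()].
#' @param x0 named initial counts (defaults to `network$initial_state`).
#' @param t_end simulation horizon.
#' @param grid time grid for state recording (`record = "grid"`).
#' @param record `"events"` (every state change) or `"grid"`.
#' @return A `trajectory` tibble (`time` + one column per species).
#' @export
ssa_direct <- function(network, x0 = network$initial_state, t_end,
                       grid = NULL, record = c("events", "grid")) {
  stopifnot(inherits(network, "reaction_network"))
  record <- match.arg(record)
  if (is.null(x0)) abort("no initial state")
  species <- network$species
  xx <- setNames(integer(length(species)), species)
  xx[names(x0)] <- as.integer(x0)
  enc <- encode_reactions(species, network$reactions$r_stoich,
                          network$reactions$p_stoich,
                          network$reactions$rate,
                          network$reactions$propensity)
  if (is.null(grid)) grid <- if (record == "grid")
    seq(0, t_end, length.out = 101L) else numeric(0)
  res <- ssa_core(xx, t_end, enc$react, enc$change,
                  network$reactions$rate, enc$ptype, enc$ppar,
                  grid, record == "events")
  make_trajectory(res, species, grid, record, "ssa_full", xx)
}

delay_spec_for <- function(d) {
  if (is.null(d)) return(list(type = 0L, rates = 1))
  switch(d$rep$type,
    stage_rates = list(type = 0L, rates = d$rep$rates),
    residue = list(type = 1L, terms = d$rep$terms,
                   scale = distribution_scale(d)),
    tabulated = list(type = 2L, time = d$rep$time, cdf = d$rep$cdf)
  )
}

encode_abridged <- function(abridged) {
  species <- abridged$species
  im <- abridged$immediate
  dd <- abridged$delayed
  r_st <- c(im$r_stoich, dd$r_stoich)
  p_st <- c(im$p_stoich, dd$p_stoich)
  rates <- c(im$rate, dd$rate)
  props <- c(im$propensity, dd$propensity)
  enc <- encode_reactions(species, r_st, p_st, rates, props)
  nr <- length(rates)
  nim <- nrow(im)
  is_delayed <- c(rep(FALSE, nim), rep(TRUE, nrow(dd)))
  # increment columns: one per distinct delayed-product multiset
  inc_key <- vapply(dd$p_stoich, function(p) paste(sort(paste(p, names(p))),
                                                   collapse = "+"), character(1))
  keys <- unique(inc_key[vapply(dd$p_stoich, length, integer(1)) > 0])
  increments <- matrix(0L, length(species), max(length(keys), 1L))
  for (k in seq_along(keys)) {
    p <- dd$p_stoich[[match(keys[k], inc_key)]]
    increments[match(names(p), species), k] <- as.integer(p)
  }
  inc_col <- c(rep(-1L, nim), ifelse(inc_key %in% keys,
                                     match(inc_key, keys) - 1L, -1L))
  specs <- c(rep(list(list(type = 0L, rates = 1)), nim),
             lapply(dd$delay, delay_spec_for))
  list(enc = enc, rates = rates, is_delayed = is_delayed, inc_col = inc_col,
       increments = increments, inc_keys = keys, specs = specs)
}

history_columns <- function(history, species, increments, keys) {
  if (is.null(history) || nrow(history$pending) == 0L) {
    return(list(times = numeric(0), cols = integer(0),
                increments = increments))
  }
  hk <- vapply(history$pending$p_stoich,
               function(p) paste(sort(paste(p, names(p))), collapse = "+"),
               character(1))
  for (k in setdiff(unique(hk), keys)) {
    p <- history$pending$p_stoich[[match(k, hk)]]
    col <- integer(nrow(increments))
    col[match(names(p), species)] <- as.integer(p)
    increments <- cbind(increments, col)
    keys <- c(keys, k)
  }
  list(times = history$pending$time, cols = match(hk, keys) - 1L,
       increments = increments)
}

#' Rejection-method delay SSA on an abridged model
#'
#' Exact delay stochastic simulation with consuming delayed reactions:
#' a tentative next-reaction time is drawn from the total propensity; if a
#' queued product completion precedes it, the tentative firing is rejected,
#' the state advances to the completion, and the waiting time is redrawn
#' (valid by memorylessness). Firing a delayed reaction removes its
#' reactants immediately and enqueues the products at `t + tau` with `tau`
#' drawn from the reaction's delay distribution. Completions tied with a
#' tentative firing go first; pending updates beyond `t_end` are discarded
#' from the reported trajectory.
#'
#' @param abridged an `abridged_model`.
#' @param t_end horizon.
#' @param x0 named initial counts on the abridged species (defaults to the
#'   history's initial state, then the model's).
#' @param history optional `history_draw` from [build_initial_history()].
#' @param grid,record as in [ssa_direct()].
#' @return A `trajectory` tibble.
#' @export
dssa_rejection <- function(abridged, t_end, x0 = NULL, history = NULL,
                           grid = NULL, record = c("events", "grid")) {
  stopifnot(inherits(abridged, "abridged_model"))
  record <- match.arg(record)
  species <- abridged$species
  if (is.null(x0)) {
    x0 <- if (!is.null(history)) history$initial_state else abridged$initial_state
  }
  if (is.null(x0)) abort("no initial state")
  xx <- setNames(integer(length(species)), species)
  xx[names(x0)] <- as.integer(x0)
  code <- encode_abridged(abridged)
  h <- history_columns(history, species, code$increments, code$inc_keys)
  if (is.null(grid)) grid <- if (record == "grid")
    seq(0, t_end, length.out = 101L) else numeric(0)
  res <- dssa_core(xx, t_end, code$enc$react, code$enc$change, code$rates,
                   code$enc$ptype, code$enc$ppar, code$is_delayed,
                   code$inc_col, h$increments, code$specs,
                   h$times, h$cols, grid, record == "events")
  make_trajectory(res, species, grid, record, "dssa_abridged", xx)
}

#' Simulate an ensemble of runs on a common time grid
#'
#' Runs `n` independent simulations (SSA for a `reaction_network`, DSSA for
#' an `abridged_model`), records states on `grid`, and accumulates running
#' means and variances plus the terminal state of every run. When
#' `history_state` is given (an initial state of the *full* model), a fresh
#' delay history is drawn before each DSSA run, consuming the same RNG
#' stream.
#'
#' @param model a `reaction_network` or `abridged_model`.
#' @param n number of runs.
#' @param t_end horizon.
#' @param grid recording grid (default 21 equispaced checkpoints).
#' @param x0 initial state (named).
#' @param history_state full-model initial state from which to draw the
#'   delay history each run (abridged models only).
#' @return An `ensemble` object with elements `grid`, `species`, `mean`,
#'   `var`, `terminal` (runs x species) and `n`.
#' @export
simulate_ensemble <- function(model, n, t_end, grid = seq(0, t_end, length.out = 21L),
                              x0 = NULL, history_state = NULL) {
  is_abr <- inherits(model, "abridged_model")
  species <- model$species
  nsp <- length(species)
  ng <- length(grid)
  mu <- matrix(0, ng, nsp, dimnames = list(NULL, species))
  m2 <- matrix(0, ng, nsp, dimnames = list(NULL, species))
  terminal <- matrix(0L, n, nsp, dimnames = list(NULL, species))
  for (i in seq_len(n)) {
    tr <- if (is_abr) {
      hist <- if (!is.null(history_state))
        build_initial_history(model$network, model, history_state) else NULL
      dssa_rejection(model, t_end, x0 = x0, history = hist,
                     grid = grid, record = "grid")
    } else {
      ssa_direct(model, x0 = if (is.null(x0)) model$initial_state else x0,
                 t_end = t_end, grid = grid, record = "grid")
    }
    st <- as.matrix(tr[, species])
    delta <- st - mu
    mu <- mu + delta / i
    m2 <- m2 + delta * (st - mu)
    terminal[i, ] <- st[ng, ]
  }
  structure(list(grid = grid, species = species, mean = mu,
                 var = if (n > 1) m2 / (n - 1) else m2 * NA,
                 terminal = terminal, n = n,
                 model_id = if (is_abr) "dssa_abridged" else "ssa_full"),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble> ", x$n, " runs of ", x$model_id, ", ",
      length(x$grid), " checkpoints\n", sep = "")
  cat("  terminal means:",
      paste(x$species, round(colMeans(x$terminal), 2), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.ensemble <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$mean))
  out$time <- x$grid
  out <- tidyr::pivot_longer(out, -"time", names_to = "species",
                             values_to = "mean")
  v <- tibble::as_tibble(as.data.frame(x$var))
  v$time <- x$grid
  v <- tidyr::pivot_longer(v, -"time", names_to = "species",
                           values_to = "var")
  out$var <- v$var
  out$se <- sqrt(out$var / x$n)
  out
}

#' Write a trajectory as TSV (`time` column + one column per species)
#' @param traj a `trajectory`.
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write ensemble summary TSV (time, per-species mean and variance, n)
#' @param ens an `ensemble`.
#' @param path output file.
#' @export
write_ensemble <- function(ens, path) {
  df <- data.frame(time = ens$grid)
  for (s in ens$species) {
    df[[paste0("mean_", s)]] <- ens$mean[, s]
    df[[paste0("var_", s)]] <- ens$var[, s]
  }
  df$n <- ens$n
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
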