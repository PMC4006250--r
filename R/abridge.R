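# Abridgement: replace the lumped intermediate block by consuming delayed
# reactions between SOIs with probability-weighted rates.

#' Abridge a reaction network for a chosen SOI set
#'
#' Replaces every non-SOI chain species by consuming delayed reactions among
#' the SOIs. Each reaction taking SOI reactants into the block ("entry", e.g.
#' \eqn{S_1 \to S_2}) is split over the block's exit channels: for a channel
#' with products \eqn{P} and event probability \eqn{p} it contributes a
#' consuming delayed reaction (entry reactants) \eqn{\to P} with rate
#' `entry rate * p` and the conditional first-passage delay of that channel.
#' A channel that restores the entry reactants is a first-return loop; one
#' that produces the opposite SOI is a first-arrival link. Degradation inside
#' the block becomes a delayed loss reaction (reactants removed, no product),
#' so the outgoing rates of each SOI sum exactly to the original outgoing
#' rate. Reactions entirely among SOIs (direct \eqn{S_1 \leftrightarrow S_n}
#' conversions, SOI synthesis/degradation, boundary bimolecular reactions)
#' are carried over verbatim.
#'
#' With two boundary SOIs this yields the classical four delayed reactions
#' (two first-return loops, two first-arrival links); with a single SOI it
#' yields one first-return loop per outgoing reaction of that SOI, whose
#' delay also counts walks through the far chain end.
#'
#' @param network a [reaction_network()].
#' @param sois species of interest (defaults to `network$sois`).
#' @param mode `"auto"`, `"two_soi"` or `"single_soi"`; checked against
#'   `sois` but the construction is the same.
#' @param allow_soi_bypass allow bypass reactions taking an SOI into the
#'   block (handled by the general minor machinery / numeric fallback);
#'   off by default.
#' @param syntheses attach delayed synthesis reactions for block-producing
#'   syntheses (see [attach_synthesis()]).
#' @return An `abridged_model`.
#' @export
abridge <- function(network, sois = network$sois,
                    mode = c("auto", "two_soi", "single_soi"),
                    allow_soi_bypass = FALSE, syntheses = TRUE) {
  mode <- match.arg(mode)
  report <- classify_reactions(network, sois)
  n_chain_soi <- length(intersect(sois, report$chain_order))
  if (mode == "two_soi" && n_chain_soi < 2L) {
    abort("two_soi mode needs two SOIs on the chain")
  }
  if (mode == "single_soi" && n_chain_soi != 1L) {
    abort("single_soi mode needs exactly one chain SOI")
  }
  if (report$flags$bypass_touches_soi && !allow_soi_bypass) {
    abort(paste0("unsupported configuration: a bypass reaction takes an SOI ",
                 "into the lumped block; set allow_soi_bypass = TRUE to use ",
                 "the general machinery"))
  }

  inner <- inner_block(network, absorbing = sois, report = report)
  rx <- report$reactions
  block <- inner$species
  bpos <- setNames(seq_along(block), block)

  is_soi_only <- vapply(seq_len(nrow(rx)), function(i) {
    all(names(rx$r_stoich[[i]]) %in% sois) &&
      all(names(rx$p_stoich[[i]]) %in% sois)
  }, logical(1))
  immediate <- rx[is_soi_only, ]

  is_entry <- vapply(seq_len(nrow(rx)), function(i) {
    r <- rx$r_stoich[[i]]; p <- rx$p_stoich[[i]]
    n_reactant_molecules(r) >= 1 && all(names(r) %in% sois) &&
      length(p) >= 1L && any(names(p) %in% block)
  }, logical(1))

  delayed <- list()
  prob_rows <- list()
  for (i in which(is_entry)) {
    r <- rx$r_stoich[[i]]; p <- rx$p_stoich[[i]]
    if (length(p) != 1L || p[[1]] != 1) {
      abort(paste0("entry reaction ", i, " must have a single unit-",
                   "stoichiometry product inside the block"))
    }
    a <- bpos[[names(p)]]
    probs <- absorb_probs(inner, a)
    for (ci in seq_along(inner$channels)) {
      ch <- inner$channels[[ci]]
      pch <- probs[[ci]]
      if (pch < 1e-14) next                 # probability-zero branch dropped
      fp <- fp_distribution(inner, a, ch$beta,
                            label = paste0(rx$reactant[i], "_to_",
                                           deparse_side(ch$products)))
      lab <- if (identical(sort(names(ch$products)), sort(names(r))) &&
                 identical(unname(ch$products[sort(names(ch$products))]),
                           unname(r[sort(names(r))]))) "first_return"
             else "first_arrival"
      delayed[[length(delayed) + 1L]] <- tibble::tibble(
        reactant = rx$reactant[i], product = deparse_side(ch$products),
        rate = rx$rate[i] * pch, probability = pch,
        label = lab,
        delay = list(fp$dist),
        propensity = list(weighted_propensity(rx$propensity[[i]], pch)),
        r_stoich = list(r), p_stoich = list(ch$products)
      )
    }
    pdeg <- probs[["deg"]]
    if (pdeg > 1e-14) {
      delayed[[length(delayed) + 1L]] <- tibble::tibble(
        reactant = rx$reactant[i], product = "", rate = rx$rate[i] * pdeg,
        probability = pdeg, label = "loss", delay = list(NULL),
        propensity = list(weighted_propensity(rx$propensity[[i]], pdeg)),
        r_stoich = list(r), p_stoich = list(setNames(numeric(0), character(0)))
      )
    }
    prob_rows[[length(prob_rows) + 1L]] <-
      tibble::tibble(entry = rx$reactant[i], start = names(p),
                     p_channels = list(probs))
  }

  species <- unique(c(
    sois,
    unlist(lapply(immediate$r_stoich, names)),
    unlist(lapply(immediate$p_stoich, names)),
    unlist(lapply(delayed, function(d) c(names(d$r_stoich[[1]]),
                                         names(d$p_stoich[[1]]))))
  ))

  out <- structure(
    list(
      species = species,
      sois = sois,
      delayed = if (length(delayed)) dplyr::bind_rows(delayed) else
        tibble::tibble(reactant = character(), product = character(),
                       rate = numeric(), probability = numeric(),
                       label = character(), delay = list(),
                       propensity = list(), r_stoich = list(),
                       p_stoich = list()),
      immediate = immediate,
      inner = inner,
      entry_probabilities = if (length(prob_rows)) dplyr::bind_rows(prob_rows)
        else NULL,
      probabilities = if (n_chain_soi == 2L && !no_intermediates(inner))
        tryCatch(arrival_return_probabilities(
          inner_rate_matrix_like(inner)), error = function(e) NULL)
        else NULL,
      network = network,
      fp_cache = new.env(parent = emptyenv()),
      initial_state = if (!is.null(network$initial_state))
        network$initial_state[intersect(names(network$initial_state), species)]
        else NULL,
      synthesis_attached = FALSE
    ),
    class = "abridged_model"
  )
  if (syntheses) out <- attach_synthesis(network, out)
  out
}

# arrival_return_probabilities expects a two-boundary inner matrix; the
# inner block built here is identical, so just hand it over
inner_rate_matrix_like <- function(inner) inner

weighted_propensity <- function(prop, w) {
  if (is.null(prop)) return(NULL)
  prop$weight <- (if (is.null(prop$weight)) 1 else prop$weight) * w
  prop
}

#' Rewire synthesis reactions into the abridged model
#'
#' SOI-producing syntheses are already carried over by [abridge()]. A
#' synthesis \eqn{\emptyset \to S_i} producing a lumped intermediate is
#' replaced by delayed syntheses \eqn{\emptyset \to} (channel products), one
#' per exit channel reachable from \eqn{S_i}, with rates weighted by the
#' arrival probabilities and the conditional first-arrival delays from
#' \eqn{S_i}; the degradation-absorbed fraction emits nothing and is
#' dropped.
#'
#' @param network the original [reaction_network()].
#' @param abridged an `abridged_model`.
#' @return The updated `abridged_model`.
#' @export
attach_synthesis <- function(network, abridged) {
  stopifnot(inherits(abridged, "abridged_model"))
  if (isTRUE(abridged$synthesis_attached)) return(abridged)
  inner <- abridged$inner
  block <- inner$species
  bpos <- setNames(seq_along(block), block)
  rx <- network$reactions
  add <- list()
  for (i in seq_len(nrow(rx))) {
    r <- rx$r_stoich[[i]]; p <- rx$p_stoich[[i]]
    if (n_reactant_molecules(r) != 0L || length(p) == 0L) next
    if (!any(names(p) %in% block)) next      # SOI synthesis: already immediate
    if (length(p) != 1L || p[[1]] != 1) {
      abort(paste0("synthesis reaction ", i, " must produce a single molecule"))
    }
    a <- bpos[[names(p)]]
    probs <- absorb_probs(inner, a)
    for (ci in seq_along(inner$channels)) {
      ch <- inner$channels[[ci]]
      pch <- probs[[ci]]
      if (pch < 1e-14) next
      fp <- fp_distribution(inner, a, ch$beta,
                            label = paste0("synthesis_", names(p), "_to_",
                                           deparse_side(ch$products)))
      add[[length(add) + 1L]] <- tibble::tibble(
        reactant = "", product = deparse_side(ch$products),
        rate = rx$rate[i] * pch, probability = pch,
        label = "synthesis_arrival", delay = list(fp$dist),
        propensity = list(NULL),
        r_stoich = list(setNames(numeric(0), character(0))),
        p_stoich = list(ch$products)
      )
    }
  }
  if (length(add)) abridged$delayed <- dplyr::bind_rows(abridged$delayed,
                                                        dplyr::bind_rows(add))
  abridged$synthesis_attached <- TRUE
  abridged
}

#' Draw the initial-condition delay history
#'
#' Molecules sitting on lumped intermediates at time zero are invisible to
#' the abridged state; each one is converted into a pre-drawn pending update:
#' first an outcome (one of the exit channels, or degradation) is drawn from
#' the absorption probabilities starting at that species, then for
#' non-degradation outcomes a completion time is drawn from the conditional
#' first-arrival distribution. Draws consume R's global RNG, before the
#' simulation loop, so a run is reproducible from one seed.
#'
#' @param network the original full model.
#' @param abridged the `abridged_model`.
#' @param full_initial_state named counts on the original species.
#' @return A `history_draw`: tibble `pending` (completion time + products),
#'   `discarded` count, and the SOI part of the initial state.
#' @export
build_initial_history <- function(network, abridged, full_initial_state) {
  stopifnot(inherits(abridged, "abridged_model"))
  if (is.null(names(full_initial_state))) abort("initial state must be named")
  unknown <- setdiff(names(full_initial_state), network$species)
  if (length(unknown)) {
    abort(paste0("initial molecules of species not in the model: ",
                 paste(unknown, collapse = ", ")))
  }
  inner <- abridged$inner
  block <- inner$species
  bpos <- setNames(seq_along(block), block)
  off_block <- setdiff(names(full_initial_state), c(abridged$species, block))
  if (any(full_initial_state[off_block] > 0)) {
    abort("initial molecules on species that are neither SOIs nor lumped intermediates")
  }

  x0 <- setNames(numeric(length(abridged$species)), abridged$species)
  keep <- intersect(names(full_initial_state), abridged$species)
  x0[keep] <- full_initial_state[keep]

  cache <- abridged$fp_cache
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  cached_fp <- function(a, ci) {
    key <- paste0("s", a, "c", ci)
    if (!exists(key, envir = cache, inherits = FALSE)) {
      assign(key, fp_distribution(inner, a, inner$channels[[ci]]$beta),
             envir = cache)
    }
    get(key, envir = cache, inherits = FALSE)
  }

  pending <- list()
  discarded <- 0L
  for (s in intersect(names(full_initial_state), block)) {
    cnt <- full_initial_state[[s]]
    if (cnt <= 0) next
    a <- bpos[[s]]
    probs <- absorb_probs(inner, a)
    draws <- as.vector(rmultinom(1L, cnt, pmax(probs, 0)))
    nch <- length(inner$channels)
    for (ci in seq_len(nch)) {
      k <- draws[ci]
      if (k == 0L) next
      fp <- cached_fp(a, ci)
      pending[[length(pending) + 1L]] <- tibble::tibble(
        time = sample_delay(fp$dist, k),
        product = deparse_side(inner$channels[[ci]]$products),
        p_stoich = rep(list(inner$channels[[ci]]$products), k),
        origin = s
      )
    }
    discarded <- discarded + draws[nch + 1L]
  }
  pending <- if (length(pending)) {
    dplyr::arrange(dplyr::bind_rows(pending), .data$time)
  } else {
    tibble::tibble(time = numeric(), product = character(),
                   p_stoich = list(), origin = character())
  }
  structure(list(pending = pending, discarded = discarded,
                 initial_state = x0),
            class = "history_draw")
}

#' @export
print.abridged_model <- function(x, ...) {
  cat("<abridged_model> SOIs:", paste(x$sois, collapse = ", "), "\n")
  cat("  ", nrow(x$delayed), " delayed + ", nrow(x$immediate),
      " immediate reactions; ", length(x$inner$species),
      " species lumped\n", sep = "")
  for (i in seq_len(nrow(x$delayed))) {
    d <- x$delayed[i, ]
    cat(sprintf("  [%s] %s -> %s  rate %.6g%s\n", d$label,
                ifelse(nzchar(d$reactant), d$reactant, "0"),
                ifelse(nzchar(d$product), d$product, "0"), d$rate,
                if (!is.null(d$delay[[1]]))
                  paste0("  delay mean ",
                         signif(distribution_mean(d$delay[[1]]), 4))
                else ""))
  }
  invisible(x)
}

#' @export
tidy.abridged_model <- function(x, ...) {
  dd <- dplyr::select(x$delayed, "reactant", "product", "rate",
                      "probability", "label")
  dd$delay_mean <- vapply(x$delayed$delay, function(d) {
    if (is.null(d)) NA_real_ else distribution_mean(d)
  }, numeric(1))
  ii <- dplyr::select(x$immediate, "reactant", "product", "rate")
  ii$probability <- NA_real_
  ii$label <- "immediate"
  ii$delay_mean <- NA_real_
  dplyr::bind_rows(dd, ii)
}

#' @export
glance.abridged_model <- function(x, ...) {
  tibble::tibble(
    n_species_full = length(x$network$species),
    n_species_abridged = length(x$species),
    n_lumped = length(x$inner$species),
    n_delayed = nrow(x$delayed),
    n_immediate = nrow(x$immediate)
  )
}

#' Serialize an abridged model
#'
#' Same YAML layout as [write_model()] with an extra `delay` block per
#' delayed reaction: a closed-form descriptor (stage rates or residue terms)
#' or a reference to an exported tabulation TSV.
#'
#' @param abridged an `abridged_model`.
#' @param path output file.
#' @param dist_dir where tabulated delays are exported (default: next to
#'   `path`).
#' @export
write_abridged_model <- function(abridged, path, dist_dir = dirname(path)) {
  rx <- lapply(seq_len(nrow(abridged$delayed)), function(i) {
    d <- abridged$delayed[i, ]
    out <- list(reactant = d$reactant, product = d$product, rate = d$rate,
                label = d$label)
    dd <- d$delay[[1]]
    if (!is.null(dd)) {
      out$delay <- switch(dd$rep$type,
        stage_rates = list(type = "stage_rates", rates = as.list(dd$rep$rates)),
        residue = list(type = "residue",
                       terms = apply(dd$rep$terms, 1, as.list, simplify = FALSE)),
        tabulated = {
          f <- file.path(dist_dir, paste0("delay_", i, ".tsv"))
          write_distribution(dd, f)
          list(type = "tabulated", file = basename(f))
        })
    }
    out
  })
  im <- lapply(seq_len(nrow(abridged$immediate)), function(i) {
    r <- abridged$immediate[i, ]
    list(reactant = r$reactant, product = r$product, rate = r$rate)
  })
  cfg <- list(species = as.list(abridged$species),
              sois = as.list(abridged$sois),
              delayed_reactions = rx, reactions = im)
  writeLines(yaml::as.yaml(cfg, precision = 15), path)
  invisible(path)
}
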