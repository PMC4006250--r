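# Generator matrices (column convention: d p/dt = K p) and the inner rate
# matrix of the lumped intermediates.

#' Build the generator matrix of a monomolecular network
#'
#' Column-generator convention: entry \eqn{(i, j)}, \eqn{i \ne j}, is the
#' summed rate of reactions \eqn{S_j \to S_i}; the diagonal \eqn{(j, j)} is
#' minus the total outflow rate of \eqn{S_j} (including degradation).
#' Columns of absorbing species are zeroed. With `lump_degradation`, an extra
#' row/column collects all degradation flux into one common absorbing state
#' named `"*deg*"`.
#'
#' Boundary bimolecular reactions (all reactants SOIs) and synthesis
#' reactions are not walker moves and never enter the matrix; any other
#' non-unimolecular reaction is an error.
#'
#' @param network a [reaction_network()].
#' @param absorbing species treated as absorbing boundaries.
#' @param lump_degradation append the common absorbing degradation state?
#' @return A `generator_matrix`: the matrix plus the species ordering map.
#' @export
build_generator <- function(network, absorbing = character(),
                            lump_degradation = FALSE) {
  stopifnot(inherits(network, "reaction_network"))
  sp <- network$species
  if (!all(absorbing %in% sp)) abort("unknown species in `absorbing`")
  pos <- setNames(seq_along(sp), sp)
  n <- length(sp)
  K <- matrix(0, n, n, dimnames = list(sp, sp))
  deg <- setNames(numeric(n), sp)

  for (i in seq_len(nrow(network$reactions))) {
    r <- network$reactions$r_stoich[[i]]
    p <- network$reactions$p_stoich[[i]]
    rate <- network$reactions$rate[i]
    nr <- n_reactant_molecules(r)
    if (nr == 0L) next                       # synthesis: not a walker move
    if (nr > 1L) {
      if (all(names(r) %in% c(absorbing, network$sois))) next  # boundary bimolecular
      abort(paste0("bimolecular reaction ", i, " involves non-boundary species"))
    }
    j <- pos[[names(r)]]
    if (length(p) == 0L) {                   # degradation
      deg[j] <- deg[j] + rate
      K[j, j] <- K[j, j] - rate
    } else {
      tgt <- pos[[names(p)[1]]]              # product bursts: one walker move
      K[tgt, j] <- K[tgt, j] + rate
      K[j, j] <- K[j, j] - rate
    }
  }

  if (lump_degradation) {
    K <- rbind(cbind(K, 0), 0)
    rownames(K)[n + 1L] <- colnames(K)[n + 1L] <- "*deg*"
    K[n + 1L, seq_len(n)] <- deg
  }
  K[, intersect(absorbing, colnames(K))] <- 0

  structure(
    list(matrix = K, ordering = pos, absorbing = absorbing,
         lumped = lump_degradation, convention = "column"),
    class = "generator_matrix"
  )
}

#' @export
print.generator_matrix <- function(x, ...) {
  cat("<generator_matrix> column convention, ", nrow(x$matrix), "x",
      ncol(x$matrix), "\n", sep = "")
  print(round(x$matrix, 6))
  invisible(x)
}

#' Inner rate matrix of the intermediates between two boundary SOIs
#'
#' Restricts the generator to the intermediate species
#' \eqn{S_2 \ldots S_{n-1}}: outflow to the boundaries and to degradation
#' appears only on the diagonal, bypasses among intermediates appear as
#' off-tridiagonal entries. The eigenvalues of this matrix determine every
#' first-arrival and first-return delay in closed form.
#'
#' @param network a [reaction_network()].
#' @param sois exactly the two chain-end SOIs.
#' @return An `inner_rate_matrix`; its `channels` element maps each exit
#'   route (grouped by target/products) to the vector of absorption rates
#'   out of each intermediate.
#' @export
inner_rate_matrix <- function(network, sois = network$sois) {
  report <- classify_reactions(network, sois)
  ends <- report$chain_order[c(1L, length(report$chain_order))]
  if (length(sois) != 2L || !setequal(sois, ends)) {
    abort("inner_rate_matrix needs exactly the two chain-end SOIs")
  }
  inner_block(network, absorbing = sois, report = report)
}

# Generator restricted to an arbitrary block of non-absorbing species, with
# exit channels. A channel groups all block-exit reactions by their product
# multiset, so e.g. every dissociation C_i -> T + M feeds one channel.
inner_block <- function(network, absorbing, report = NULL,
                        block = NULL) {
  sp <- network$species
  if (is.null(block)) {
    # the walker's state space: non-absorbing species with unimolecular
    # outflow (species that only take part in boundary bimolecular reactions
    # are free binding partners, not walker positions)
    block <- setdiff(sp, absorbing)
    outflow <- vapply(block, function(s) {
      sum(vapply(seq_len(nrow(network$reactions)), function(i) {
        st <- network$reactions$r_stoich[[i]]
        if (identical(names(st), s) && st[[1]] == 1) network$reactions$rate[i] else 0
      }, numeric(1)))
    }, numeric(1))
    block <- block[outflow > 0]
  }
  m <- length(block)
  if (m == 0L) {
    return(structure(list(matrix = matrix(0, 0, 0), species = character(0),
                          channels = list(), deg = numeric(0)),
                     class = c("inner_rate_matrix")))
  }
  bpos <- setNames(seq_len(m), block)
  K <- matrix(0, m, m, dimnames = list(block, block))
  deg <- setNames(numeric(m), block)
  channels <- list()

  for (i in seq_len(nrow(network$reactions))) {
    r <- network$reactions$r_stoich[[i]]
    p <- network$reactions$p_stoich[[i]]
    rate <- network$reactions$rate[i]
    if (n_reactant_molecules(r) != 1L || !(names(r) %in% block)) next
    j <- bpos[[names(r)]]
    K[j, j] <- K[j, j] - rate
    if (length(p) == 0L) {                    # degradation: killing
      deg[j] <- deg[j] + rate
    } else if (all(names(p) %in% block)) {    # interior move
      if (length(p) > 1L) abort(paste0("unsupported reaction ", i,
                                       ": multiple products inside the block"))
      K[bpos[[names(p)]], j] <- K[bpos[[names(p)]], j] + rate
    } else if (all(names(p) %in% absorbing) ||
               !any(names(p) %in% block)) {   # exit channel
      key <- paste(sort(paste(p, names(p))), collapse = "+")
      if (is.null(channels[[key]])) {
        channels[[key]] <- list(
          target = names(p)[1], products = p,
          beta = setNames(numeric(m), block)
        )
      }
      channels[[key]]$beta[j] <- channels[[key]]$beta[j] + rate
    } else {
      abort(paste0("unsupported reaction ", i,
                   ": products straddle the block boundary"))
    }
  }

  tri <- all(K[row(K) - col(K) > 1L] == 0) && all(K[col(K) - row(K) > 1L] == 0)
  unidir <- all(K[col(K) - row(K) >= 1L] == 0) || all(K[row(K) - col(K) >= 1L] == 0)

  structure(
    list(matrix = K, species = block, channels = channels, deg = deg,
         tridiagonal = tri, unidirectional = unidir,
         absorbing = absorbing),
    class = "inner_rate_matrix"
  )
}

#' @export
print.inner_rate_matrix <- function(x, ...) {
  m <- length(x$species)
  if (m == 0L) {
    cat("<inner_rate_matrix> no intermediates\n")
    return(invisible(x))
  }
  cat("<inner_rate_matrix> ", m, "x", m,
      if (isTRUE(x$tridiagonal)) " (tridiagonal)" else "", "\n", sep = "")
  print(round(x$matrix, 6))
  cat("  exit channels:", paste(names(x$channels), collapse = ", "), "\n")
  if (any(x$deg > 0)) cat("  degradation rates present\n")
  invisible(x)
}

no_intermediates <- function(inner) length(inner$species) == 0L
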