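# Reaction networks: species, monomolecular reactions with optional boundary
# bimolecular reactions, designated species of interest (SOIs).

#' Construct a reaction network
#'
#' A reaction network is the full (unabridged) model: an ordered list of
#' species, a table of reactions, and optionally a set of species of interest
#' (SOIs) whose marginal dynamics an abridged model must preserve. The species
#' order defines the chain coordinate \eqn{S_1 \ldots S_n}: reactions between
#' adjacent species are chain reactions, reactions spanning more than one
#' position are bypasses.
#'
#' Reaction sides are written as `"S1"`, `"2 Y"`, `"T + M"` or `""` (nothing,
#' for synthesis/degradation). Mass-action kinetics are assumed; a reaction
#' may instead carry a state-dependent propensity in the `propensity`
#' list-column (see [propensity_saturating()]).
#'
#' @param reactions data frame with columns `reactant`, `product` (character
#'   stoichiometry strings), `rate` (nonnegative), and optionally `kind` and
#'   `propensity` (list-column).
#' @param species character vector fixing the species order; inferred from
#'   order of first appearance when `NULL`.
#' @param sois character vector of species of interest.
#' @param initial_state named numeric vector of molecule counts.
#' @return An object of class `reaction_network`.
#' @examples
#' net <- reaction_network(
#'   tibble::tibble(
#'     reactant = c("S1", "S2", "S2", "S3"),
#'     product  = c("S2", "S1", "S3", "S2"),
#'     rate     = c(1, 2, 1, 1)
#'   ),
#'   sois = c("S1", "S3")
#' )
#' net
#' @export
reaction_network <- function(reactions, species = NULL, sois = character(),
                             initial_state = NULL) {
  stopifnot(is.data.frame(reactions))
  reactions <- tibble::as_tibble(reactions)
  if (!all(c("reactant", "product", "rate") %in% names(reactions))) {
    abort("`reactions` needs columns `reactant`, `product`, `rate`")
  }
  if (any(!is.finite(reactions$rate)) || any(reactions$rate < 0)) {
    abort("reaction rates must be finite and nonnegative")
  }
  reactions$r_stoich <- lapply(reactions$reactant, parse_side)
  reactions$p_stoich <- lapply(reactions$product, parse_side)
  if (!"kind" %in% names(reactions)) reactions$kind <- NA_character_
  if (!"propensity" %in% names(reactions)) {
    reactions$propensity <- vector("list", nrow(reactions))
  }

  seen <- unique(unlist(lapply(
    seq_len(nrow(reactions)),
    function(i) c(names(reactions$r_stoich[[i]]), names(reactions$p_stoich[[i]]))
  )))
  if (is.null(species)) {
    species <- seen
  } else if (!all(seen %in% species)) {
    abort(paste0("unknown species in reactions: ",
                 paste(setdiff(seen, species), collapse = ", ")))
  }
  if (anyDuplicated(species)) abort("species names must be unique")
  if (!all(sois %in% species)) abort("sois must be declared species")

  # a full model never contains loops S -> S; loops exist only after abridging
  for (i in seq_len(nrow(reactions))) {
    r <- reactions$r_stoich[[i]]; p <- reactions$p_stoich[[i]]
    if (length(r) == 1L && length(p) == 1L && names(r) == names(p)) {
      abort(paste0("reaction ", i, " is a self-loop ", names(r), " -> ",
                   names(p), "; loops are only valid in abridged models"))
    }
  }

  if (!is.null(initial_state)) {
    if (is.null(names(initial_state)) || !all(names(initial_state) %in% species)) {
      abort("initial_state must be named with declared species")
    }
    x0 <- setNames(numeric(length(species)), species)
    x0[names(initial_state)] <- initial_state
    initial_state <- x0
  }

  structure(
    list(species = species, reactions = reactions, sois = sois,
         initial_state = initial_state),
    class = "reaction_network"
  )
}

parse_side <- function(s) {
  if (is.na(s) || !nzchar(trimws(s)) || identical(trimws(s), "0")) {
    return(setNames(numeric(0), character(0)))
  }
  parts <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  out <- numeric(0)
  for (p in parts) {
    m <- regmatches(p, regexec("^([0-9]+)?\\s*([A-Za-z][A-Za-z0-9_.]*)$", p))[[1]]
    if (length(m) == 0L) abort(paste0("cannot parse stoichiometry term '", p, "'"))
    k <- if (nzchar(m[2])) as.numeric(m[2]) else 1
    sp <- m[3]
    out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0) + k
  }
  out
}

deparse_side <- function(st) {
  if (length(st) == 0L) return("")
  paste(ifelse(st == 1, names(st), paste(st, names(st))), collapse = " + ")
}

#' State-dependent saturating (Hill-type) propensity
#'
#' Propensity \eqn{a(x) = V (\phi x)^q / (1 + (\phi x)^h)} in the copy number
#' `x` of one species, zero whenever `x` is below the reaction's reactant
#' stoichiometry. Used for the autocatalytic, product-inhibited PFK step of
#' the glycolysis example; attaches to a reaction through the `propensity`
#' list-column.
#'
#' @param species name of the species whose count drives the propensity.
#' @param V,phi,q,h positive parameters: limiting scale, concentration scale,
#'   activation exponent and inhibition exponent.
#' @export
propensity_saturating <- function(species, V, phi, q, h) {
  stopifnot(V > 0, phi > 0, q > 0, h > 0)
  structure(list(type = "saturating", species = species,
                 V = V, phi = phi, q = q, h = h),
            class = "delaychain_propensity")
}

n_reactant_molecules <- function(st) sum(st)

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$species), " species, ",
      nrow(x$reactions), " reactions\n", sep = "")
  cat("  species: ", paste(x$species, collapse = ", "), "\n", sep = "")
  if (length(x$sois)) cat("  SOIs:    ", paste(x$sois, collapse = ", "), "\n", sep = "")
  for (i in seq_len(min(nrow(x$reactions), 25L))) {
    r <- x$reactions[i, ]
    cat(sprintf("  %s -> %s  (rate %g%s)\n",
                ifelse(nzchar(r$reactant), r$reactant, "0"),
                ifelse(nzchar(r$product), r$product, "0"),
                r$rate,
                if (!is.null(r$propensity[[1]])) ", state-dependent" else ""))
  }
  if (nrow(x$reactions) > 25L) cat("  ...\n")
  invisible(x)
}

#' @export
tidy.reaction_network <- function(x, ...) {
  dplyr::select(x$reactions, "reactant", "product", "rate", "kind")
}

#' Read / write a reaction network as a model configuration file
#'
#' Models are stored as structured YAML with keys `species` (ordered list),
#' `reactions` (list of `{reactant, product, rate, kind?}`), `sois` and
#' `initial_state`. `read_model(write_model(x))` round-trips.
#'
#' @param path file path.
#' @param network a [reaction_network()].
#' @return `read_model` returns a `reaction_network`.
#' @export
read_model <- function(path) {
  cfg <- yaml::yaml.load_file(path)
  if (is.null(cfg$species)) abort(paste0("model file ", path, ": missing key `species`"))
  if (is.null(cfg$reactions)) abort(paste0("model file ", path, ": missing key `reactions`"))
  rx <- lapply(seq_along(cfg$reactions), function(i) {
    r <- cfg$reactions[[i]]
    if (is.null(r$rate)) {
      abort(paste0("model file ", path, ": reaction ", i, " is missing `rate`"))
    }
    tibble::tibble(
      reactant = if (is.null(r$reactant)) "" else as.character(r$reactant),
      product  = if (is.null(r$product)) "" else as.character(r$product),
      rate     = as.numeric(r$rate),
      kind     = if (is.null(r$kind)) NA_character_ else r$kind
    )
  })
  init <- if (is.null(cfg$initial_state)) NULL else unlist(cfg$initial_state)
  reaction_network(dplyr::bind_rows(rx), species = unlist(cfg$species),
                   sois = as.character(unlist(cfg$sois)),
                   initial_state = init)
}

#' @rdname read_model
#' @export
write_model <- function(network, path) {
  stopifnot(inherits(network, "reaction_network"))
  rx <- lapply(seq_len(nrow(network$reactions)), function(i) {
    r <- network$reactions[i, ]
    out <- list(reactant = r$reactant, product = r$product, rate = r$rate)
    if (!is.na(r$kind)) out$kind <- r$kind
    out
  })
  cfg <- list(species = as.list(network$species), reactions = rx,
              sois = as.list(network$sois))
  if (!is.null(network$initial_state)) {
    cfg$initial_state <- as.list(network$initial_state)
  }
  writeLines(yaml::as.yaml(cfg, precision = 15), path)
  invisible(path)
}
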