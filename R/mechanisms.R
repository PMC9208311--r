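#' Define a folding mechanism
#'
#' A mechanism is an ordered chain of conformational species connected by
#' reversible transitions.  Species are either dimeric (two protomers per
#' particle) or monomeric.  Exactly one transition in the chain is a
#' dissociation (dimer to two monomers); every other transition is an
#' isomerization between species of equal molecularity.  The chain runs from
#' the native (dimeric) species down to the unfolded monomer.
#'
#' @param name short identifier for the mechanism (used in configs/reports).
#' @param species data.frame with columns `name` (labels matching
#'   `[A-Za-z0-9_]+`) and `order` (protomers per particle, 1 or 2), ordered
#'   from native to unfolded.
#' @param transitions data.frame with columns `from`, `to` and `type`
#'   (`"isomerization"` or `"dissociation"`), one row per consecutive pair of
#'   species.
#' @return an object of class `mechanism`.
#' @examples
#' mechanism(
#'   "two_state",
#'   species = data.frame(name = c("N2", "U"), order = c(2, 1)),
#'   transitions = data.frame(from = "N2", to = "U", type = "dissociation")
#' )
#' @export
mechanism <- function(name, species, transitions) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  if (!all(c("name", "order") %in% names(species))) {
    stop("`species` needs columns `name` and `order`", call. = FALSE)
  }
  if (!all(c("from", "to", "type") %in% names(transitions))) {
    stop("`transitions` needs columns `from`, `to` and `type`", call. = FALSE)
  }
  if (anyDuplicated(species$name)) {
    stop("species names must be unique", call. = FALSE)
  }
  if (!all(grepl("^[A-Za-z0-9_]+$", species$name))) {
    stop("species names are restricted to [A-Za-z0-9_]", call. = FALSE)
  }
  if (!all(species$order %in% c(1L, 2L))) {
    stop("species order must be 1 (monomer) or 2 (dimer)", call. = FALSE)
  }
  n <- nrow(species)
  if (nrow(transitions) != n - 1L || n < 2L) {
    stop("transitions must chain all species: need nrow(species) - 1 rows",
         call. = FALSE)
  }
  if (!identical(transitions$from, species$name[-n]) ||
      !identical(transitions$to, species$name[-1L])) {
    stop("transitions must follow the species order: from[i] = species[i], ",
         "to[i] = species[i + 1]", call. = FALSE)
  }
  if (!all(transitions$type %in% c("isomerization", "dissociation"))) {
    stop("transition type must be 'isomerization' or 'dissociation'",
         call. = FALSE)
  }
  ord_from <- species$order[-n]
  ord_to <- species$order[-1L]
  is_diss <- transitions$type == "dissociation"
  if (sum(is_diss) != 1L) {
    stop("a mechanism chain must contain exactly one dissociation", call. = FALSE)
  }
  if (any(is_diss & !(ord_from == 2L & ord_to == 1L))) {
    stop("dissociation must go from a dimeric to a monomeric species",
         call. = FALSE)
  }
  if (any(!is_diss & ord_from != ord_to)) {
    stop("isomerization requires equal molecularity on both sides",
         call. = FALSE)
  }
  structure(
    list(name = name, species = species, transitions = transitions),
    class = "mechanism"
  )
}

#' @export
print.mechanism <- function(x, ...) {
  arrows <- ifelse(x$transitions$type == "dissociation", " = 2 ", " = ")
  chain <- x$species$name[1L]
  for (i in seq_len(nrow(x$transitions))) {
    chain <- paste0(chain, arrows[i], x$species$name[i + 1L])
  }
  cat("<mechanism> ", x$name, ": ", chain, "\n", sep = "")
  invisible(x)
}

n_transitions <- function(mech) nrow(mech$transitions)

dissociation_index <- function(mech) {
  which(mech$transitions$type == "dissociation")
}

#' Built-in mechanisms
#'
#' The registry ships the three chains used for effector-procaspase
#' unfolding:
#' \describe{
#'   \item{`three_state`}{N2 = I2 = 2U: the native dimer isomerizes to a
#'     dimeric intermediate which dissociates and unfolds in one step.}
#'   \item{`four_state`}{N2 = I2 = I2p = 2U: a second dimeric intermediate
#'     (I2', written `I2p`) precedes unfolding.}
#'   \item{`monomer_intermediate`}{N2 = I2 = 2I = 2U: the dimeric
#'     intermediate dissociates to a partially folded protomer which then
#'     unfolds (the human procaspase-3 style chain).}
#' }
#' The species-population solver is generic over any single-chain mechanism
#' with one dissociation; these are conveniences, not limits.
#'
#' @return `mechanism_registry()` returns a named list of `mechanism`
#'   objects; `get_mechanism()` returns one by name.
#' @export
mechanism_registry <- function() {
  list(
    three_state = mechanism(
      "three_state",
      species = data.frame(name = c("N2", "I2", "U"), order = c(2L, 2L, 1L)),
      transitions = data.frame(
        from = c("N2", "I2"), to = c("I2", "U"),
        type = c("isomerization", "dissociation")
      )
    ),
    four_state = mechanism(
      "four_state",
      species = data.frame(
        name = c("N2", "I2", "I2p", "U"), order = c(2L, 2L, 2L, 1L)
      ),
      transitions = data.frame(
        from = c("N2", "I2", "I2p"), to = c("I2", "I2p", "U"),
        type = c("isomerization", "isomerization", "dissociation")
      )
    ),
    monomer_intermediate = mechanism(
      "monomer_intermediate",
      species = data.frame(
        name = c("N2", "I2", "I", "U"), order = c(2L, 2L, 1L, 1L)
      ),
      transitions = data.frame(
        from = c("N2", "I2", "I"), to = c("I2", "I", "U"),
        type = c("isomerization", "dissociation", "isomerization")
      )
    )
  )
}

#' @rdname mechanism_registry
#' @param name registry key (`"three_state"`, `"four_state"`,
#'   `"monomer_intermediate"`).
#' @export
get_mechanism <- function(name) {
  reg <- mechanism_registry()
  if (!name %in% names(reg)) {
    stop("unknown mechanism '", name, "'; registry has: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]
}

#' Read and write mechanism + parameter configurations
#'
#' Mechanisms and their thermodynamic parameters serialize to a structured
#' key-value (YAML) file so fits can be audited and re-run.
#'
#' @param mech a [mechanism()].
#' @param params optional [thermo_params()] stored alongside the mechanism.
#' @param path file path.
#' @return `read_mechanism_config()` returns `list(mechanism, params)`
#'   (params `NULL` when absent); `write_mechanism_config()` returns `path`
#'   invisibly.
#' @export
write_mechanism_config <- function(mech, path, params = NULL) {
  stopifnot(inherits(mech, "mechanism"))
  cfg <- list(
    name = mech$name,
    species = lapply(seq_len(nrow(mech$species)), function(i) {
      list(name = mech$species$name[i], order = mech$species$order[i])
    }),
    transitions = lapply(seq_len(nrow(mech$transitions)), function(i) {
      list(from = mech$transitions$from[i], to = mech$transitions$to[i],
           type = mech$transitions$type[i])
    })
  )
  if (!is.null(params)) {
    stopifnot(inherits(params, "thermo_params"))
    cfg$params <- list(
      dG0 = as.numeric(params$dG0), m = as.numeric(params$m),
      temperature = params$temperature
    )
  }
  yaml::write_yaml(cfg, path, precision = 17L)
  invisible(path)
}

#' @rdname write_mechanism_config
#' @export
read_mechanism_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  mech <- mechanism(
    cfg$name,
    species = data.frame(
      name = vapply(cfg$species, `[[`, "", "name"),
      order = vapply(cfg$species, function(s) as.integer(s$order), 1L)
    ),
    transitions = data.frame(
      from = vapply(cfg$transitions, `[[`, "", "from"),
      to = vapply(cfg$transitions, `[[`, "", "to"),
      type = vapply(cfg$transitions, `[[`, "", "type")
    )
  )
  params <- NULL
  if (!is.null(cfg$params)) {
    params <- thermo_params(
      dG0 = as.numeric(cfg$params$dG0), m = as.numeric(cfg$params$m),
      temperature = as.numeric(cfg$params$temperature)
    )
  }
  list(mechanism = mech, params = params)
}
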