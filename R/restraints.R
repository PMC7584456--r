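# Experimental contact restraints: state-tagged Calpha-Calpha upper-bound
# distance restraints (disulfide / Cd(II)-cysteine bridge / mutagenesis
# contact) with harmonic violation scoring.
#
# Upper bounds follow crosslink geometry: an extended disulfide spans
# ~7 A between Calpha atoms and a cysteine-Cd(II)-cysteine bridge
# ~10 A; with 5 A of padding for protein flexibility the bounds default
# to 12 A and 15 A respectively.

.restraint_kinds <- c("disulfide", "metal_bridge", "mutagenesis_contact")
.restraint_states <- c("closed", "open", "both")

default_bound <- function(kind) ifelse(kind == "metal_bridge", 15, 12)

new_restraint_set <- function(df, state_filter = "all") {
  need <- c("chain_a", "res_a", "chain_b", "res_b", "kind", "state",
            "bound", "source")
  df <- df[, need, drop = FALSE]
  structure(df, class = c("RestraintSet", "data.frame"),
            state_filter = state_filter)
}

#' Read a restraint table (TSV/CSV)
#'
#' Expected columns: `chain_a, res_a, chain_b, res_b, kind, state`
#' plus optional `bound` (Angstrom) and `source`. `kind` must be one of
#' `disulfide`, `metal_bridge`, `mutagenesis_contact`; `state` one of
#' `closed`, `open`, `both`. Missing bounds default by kind
#' (disulfide / mutagenesis contact: 12 A, metal bridge: 15 A).
#' Duplicate rows are dropped with a warning.
#'
#' @param path path to a tab- or comma-separated table.
#' @return a `RestraintSet` (data frame subclass).
#' @export
read_restraints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  if (!length(first) || !nzchar(trimws(first))) {
    warning("empty restraint table: ", path)
    return(new_restraint_set(data.frame(
      chain_a = character(0), res_a = integer(0), chain_b = character(0),
      res_b = integer(0), kind = character(0), state = character(0),
      bound = numeric(0), source = character(0)
    )))
  }
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("chain_a", "res_a", "chain_b", "res_b", "kind", "state")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad_kind <- which(!df$kind %in% .restraint_kinds)
  if (length(bad_kind)) {
    stop("unknown restraint kind '", df$kind[bad_kind[1]], "' in row ",
         bad_kind[1])
  }
  bad_state <- which(!df$state %in% .restraint_states)
  if (length(bad_state)) {
    stop("unknown restraint state '", df$state[bad_state[1]], "' in row ",
         bad_state[1])
  }
  if (is.null(df$bound)) df$bound <- NA_real_
  df$bound <- ifelse(is.na(df$bound), default_bound(df$kind), df$bound)
  if (any(df$bound <= 0)) stop("restraint bounds must be positive")
  if (is.null(df$source)) df$source <- ""
  dup <- duplicated(df[, c("chain_a", "res_a", "chain_b", "res_b", "kind",
                           "state", "bound")])
  if (any(dup)) {
    warning(sum(dup), " duplicated restraint row(s) removed")
    df <- df[!dup, , drop = FALSE]
  }
  new_restraint_set(df)
}

#' Filter restraints by channel state
#'
#' Keeps restraints tagged with the requested state or `both`. Mirrors
#' the compilation of separate closed- and open-state restraint lists.
#'
#' @param rs a `RestraintSet`.
#' @param state `"closed"`, `"open"`, or `"all"`.
#' @return filtered `RestraintSet`.
#' @export
filter_restraints <- function(rs, state = c("all", "closed", "open")) {
  state <- match.arg(state)
  if (state == "all") return(rs)
  keep <- rs$state == state | rs$state == "both"
  new_restraint_set(as.data.frame(rs)[keep, , drop = FALSE],
                    state_filter = state)
}

# Calpha-Calpha distance per restraint. `equiv` maps a restrained chain
# to a set of symmetry-equivalent chains (for 4:2 complexes the
# restraints were collected on a single site, so each restraint is
# evaluated against the nearest equivalent ligand copy).
restraint_distances <- function(s, rs, equiv = list()) {
  ca <- which(s$atom$name == "CA")
  key <- paste(s$atom$chain[ca], s$atom$resid[ca])
  xyz <- coords(s)[ca, , drop = FALSE]
  site <- function(chain, resid, i) {
    chains <- unique(c(chain, equiv[[chain]]))
    idx <- match(paste(chains, resid), key)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) {
      stop("no CA atom for restraint ", i, " site ", chain, ":", resid)
    }
    idx
  }
  vapply(seq_len(nrow(rs)), function(i) {
    ia <- site(rs$chain_a[i], rs$res_a[i], i)
    ib <- site(rs$chain_b[i], rs$res_b[i], i)
    min(pairdist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE]))
  }, numeric(1))
}

#' Harmonic restraint penalty
#'
#' Each restraint contributes `spring * max(0, d - bound)^2`, i.e. zero
#' below its upper bound and quadratic growth beyond it; the total is
#' the sum over restraints.
#'
#' @param s a `Structure` containing CA atoms for every restrained site.
#' @param rs a `RestraintSet`.
#' @param spring harmonic prefactor (score per square Angstrom,
#'   default 1).
#' @param equiv optional chain-equivalence map (named list) so that a
#'   restraint is satisfied by the nearest symmetry-equivalent copy.
#' @return list with `total` and `per_restraint` (data frame with
#'   `distance`, `excess`, `score`).
#' @export
restraint_penalty <- function(s, rs, spring = 1, equiv = list()) {
  if (!nrow(rs)) {
    return(list(total = 0, per_restraint = data.frame(
      distance = numeric(0), excess = numeric(0), score = numeric(0))))
  }
  d <- restraint_distances(s, rs, equiv)
  excess <- pmax(0, d - rs$bound)
  score <- spring * excess^2
  list(
    total = sum(score),
    per_restraint = data.frame(
      chain_a = rs$chain_a, res_a = rs$res_a,
      chain_b = rs$chain_b, res_b = rs$res_b,
      bound = rs$bound, distance = d, excess = excess, score = score,
      stringsAsFactors = FALSE
    )
  )
}

#' Restraint violation report
#'
#' Classifies each restraint by its excess over the upper bound:
#' `satisfied` (excess <= `medium_band[1]`), `medium`
#' (within `medium_band`), `large` (beyond `medium_band[2]`). Sorted by
#' excess, largest first.
#'
#' @inheritParams restraint_penalty
#' @param medium_band numeric length-2: the (open, closed] excess band
#'   classed as a medium violation, default (2, 5] Angstrom.
#' @return a `ViolationReport` data frame (pair, bound, distance,
#'   excess, class).
#' @export
violation_report <- function(s, rs, medium_band = c(2, 5), equiv = list()) {
  pen <- restraint_penalty(s, rs, equiv = equiv)$per_restraint
  cls <- cut(pen$excess, c(-Inf, medium_band, Inf),
             labels = c("satisfied", "medium", "large"))
  pen$class <- as.character(cls)
  pen <- pen[order(-pen$excess), , drop = FALSE]
  rownames(pen) <- NULL
  structure(pen, class = c("ViolationReport", "data.frame"))
}
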