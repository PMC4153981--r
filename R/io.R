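#' Read a reaction network from a JSON or YAML config
#'
#' The config has keys `species` (list of names), `reactions` (list of
#' `{reactants, products, rate, kind}` with stoichiometries as
#' species-to-count maps) and optionally `initial_counts`
#' (species-to-count map). Rates are plain numbers in stochastic units.
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @return list with `network` (a [reaction_network()]) and `initial`
#'   (named integer vector, or `NULL`).
#' @export
read_network_config <- function(path) {
  cfg <- read_config_file(path)
  required <- c("species", "reactions")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("network config misses field(s): ", paste(missing, collapse = ", "))
  species <- unlist(cfg$species)
  rx <- lapply(cfg$reactions, function(r) {
    bad <- setdiff(names(r), c("reactants", "products", "rate", "kind"))
    if (length(bad)) stop("unknown reaction field(s): ", paste(bad, collapse = ", "))
    reaction(unlist(r$reactants), unlist(r$products), r$rate, r$kind)
  })
  net <- reaction_network(species, rx)
  initial <- NULL
  if (!is.null(cfg$initial_counts)) {
    initial <- stats::setNames(integer(length(species)), species)
    ic <- unlist(cfg$initial_counts)
    if (!all(names(ic) %in% species))
      stop("initial_counts names unknown species")
    initial[names(ic)] <- as.integer(ic)
  }
  list(network = net, initial = initial)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
  else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else stop("unsupported config extension: .", ext, " (use json or yaml)")
}

#' Write a reaction network config
#'
#' Inverse of [read_network_config()]; round-trips the network exactly.
#'
#' @param net a [reaction_network()] or [mono_network()].
#' @param path output path (`.json`, `.yaml` or `.yml`).
#' @param initial optional named initial counts.
#' @return `path`, invisibly.
#' @export
write_network_config <- function(net, path, initial = NULL) {
  if (inherits(net, "mono_network")) net <- as_reaction_network(net)
  cfg <- list(
    species = as.list(net$species),
    reactions = lapply(net$reactions, function(r) list(
      reactants = as.list(r$reactants),
      products = as.list(r$products),
      rate = r$rate,
      kind = r$kind
    ))
  )
  if (!is.null(initial)) cfg$initial_counts <- as.list(initial)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path, precision = 17L)
  } else stop("unsupported config extension: .", ext)
  invisible(path)
}

run_config_fields <- c("network", "task", "times", "subset", "seed", "runs",
                       "eta", "t_final", "cap", "leak_tol", "out")

#' Load and validate a run configuration
#'
#' A run config bundles a network spec (inline under `network`, or a path in
#' `network`) with a `task` (`solve`, `marginal`, `equilibrium`, `ssa` or
#' `fixtures`) and task options. Defaults: `eta = 50` comparison time
#' points, `leak_tol = 1e-9`, and a time grid derived from the network's
#' relaxation time when `times`/`t_final` are omitted. Unknown keys are
#' rejected by name.
#'
#' @param path config file path (json/yaml).
#' @return validated config list of class `run_config`.
#' @export
load_config <- function(path) {
  cfg <- read_config_file(path)
  bad <- setdiff(names(cfg), run_config_fields)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$task) ||
      !cfg$task %in% c("solve", "marginal", "equilibrium", "ssa", "fixtures"))
    stop("'task' must be one of solve, marginal, equilibrium, ssa, fixtures")
  if (is.null(cfg$network) && cfg$task != "fixtures")
    stop("'network' (inline spec or path) is required")
  if (is.character(cfg$network) && length(cfg$network) == 1L) {
    nc <- read_network_config(cfg$network)
  } else if (!is.null(cfg$network)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(cfg$network, tmp, auto_unbox = TRUE, digits = NA)
    nc <- read_network_config(tmp)
  } else nc <- NULL
  if (is.null(cfg$eta)) cfg$eta <- 50L
  if (is.null(cfg$leak_tol)) cfg$leak_tol <- 1e-9
  if (!is.null(cfg$times)) {
    cfg$times <- as.numeric(unlist(cfg$times))
    if (any(cfg$times < 0) || is.unsorted(cfg$times))
      stop("'times' must be nonnegative and ascending")
  }
  cfg$parsed_network <- nc
  class(cfg) <- "run_config"
  cfg
}

#' Write distribution sequences to a tidy CSV
#'
#' One row per (time, projected state): columns `time`, one column per
#' selected species count, `probability`, `truncation_mass`. Deterministic
#' row order (time, then graded lexicographic state order); full float
#' precision so the file round-trips exactly.
#'
#' @param dists list of [lattice_dist()] (one per time point).
#' @param times numeric time grid matching `dists`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(dists, times, path) {
  if (length(dists) != length(times)) stop("'dists' and 'times' must match")
  blocks <- lapply(seq_along(times), function(i) {
    d <- dists[[i]]
    o <- grlex_order(d$support)
    sup <- d$support[o, , drop = FALSE]
    cn <- colnames(sup)
    if (is.null(cn)) cn <- paste0("s", seq_len(ncol(sup)))
    df <- data.frame(time = times[i], sup, d$mass[o], d$truncation_mass)
    names(df) <- c("time", cn, "probability", "truncation_mass")
    df
  })
  out <- do.call(rbind, blocks)
  utils::write.csv(format(out, digits = 17L, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a [write_results()] CSV
#'
#' @param path CSV path.
#' @return list with `times` and `dists` (list of [lattice_dist()]).
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  spcols <- setdiff(names(df), c("time", "probability", "truncation_mass"))
  times <- unique(df$time)
  dists <- lapply(times, function(t) {
    blk <- df[df$time == t, , drop = FALSE]
    lattice_dist(as.matrix(blk[spcols]), blk$probability,
                 truncation_mass = blk$truncation_mass[1L],
                 species = spcols)
  })
  list(times = times, dists = dists)
}
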