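# Plain-text readers and writers: network config (JSON), threshold
# trains (CSV, seconds), collision logs (CSV) and run manifests (JSON).
# Times are serialised in seconds at full double precision; the readers
# reject anything the writers cannot produce.

.network_format_version <- 1L

#' Write / read a network model (JSON)
#'
#' The schema is versioned (`format_version`): `refractory_s`, `nodes`
#' (`id`, `kind`) and `neurites` (`id`, `from`, `to`, `length_m`,
#' `velocity_mps`, optional `refractory_s`).  Reading validates the
#' model and fails with an itemised message naming every offending
#' element.
#'
#' @param network A [cap_network()].
#' @param path File path.
#' @return `read_network()` returns a validated [cap_network()];
#'   `write_network()` returns `path` invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "cap_network"))
  neurites <- network$neurites
  if (all(is.na(neurites$refractory_s))) neurites$refractory_s <- NULL
  jsonlite::write_json(
    list(format_version = .network_format_version,
         refractory_s = network$refractory_s,
         nodes = network$nodes,
         neurites = neurites),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e)
                    stop_validation("cannot parse '", path, "': ",
                                    conditionMessage(e)))
  if (is.null(obj$format_version) ||
      obj$format_version != .network_format_version)
    stop_validation("'", path, "': unsupported or missing format_version")
  for (fld in c("refractory_s", "nodes", "neurites"))
    if (is.null(obj[[fld]]))
      stop_validation("'", path, "': missing field '", fld, "'")
  ne <- as.data.frame(obj$neurites)
  for (cc in c("id", "from", "to", "length_m", "velocity_mps")) {
    if (!cc %in% names(ne))
      stop_validation("'", path, "': neurites lack column '", cc, "'")
    bad <- is.na(ne[[cc]])
    if (any(bad))
      stop_validation("'", path, "': neurite(s) ",
                      paste(ne$id[bad], collapse = ", "),
                      " missing '", cc, "'")
  }
  net <- cap_network(as.data.frame(obj$nodes), ne, obj$refractory_s)
  assert_network(net)
}

#' Write / read threshold trains (CSV)
#'
#' Two columns with header: `location` (node id) and `time_s`.  Times
#' are written at 17 significant digits so a write/read round trip is
#' exact.  Reading requires, per location, strictly increasing times
#' (duplicates are an error) and -- when `refractory_s` is supplied --
#' refractory separation; violations are reported with the offending
#' rows.
#'
#' @param trains Named list of numeric time vectors.
#' @param path File path.
#' @param refractory_s Optional refractory duration for the separation
#'   check on read.
#' @return `read_trains()` returns a named list of time vectors;
#'   `write_trains()` returns `path` invisibly.
#' @export
write_trains <- function(trains, path) {
  if (!length(trains)) {
    writeLines("location,time_s", path)
    return(invisible(path))
  }
  df <- data.frame(
    location = rep(names(trains), lengths(trains)),
    time_s = vapply(unlist(trains, use.names = FALSE), function(t)
      format(t, digits = 17, scientific = FALSE), character(1)),
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trains
#' @export
read_trains <- function(path, refractory_s = NULL) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop_validation("cannot parse '", path, "': ",
                                   conditionMessage(e)))
  if (!all(c("location", "time_s") %in% names(df)))
    stop_validation("'", path, "': need header columns location, time_s")
  if (!nrow(df)) return(stats::setNames(list(), character()))
  if (!is.numeric(df$time_s) || any(!is.finite(df$time_s)))
    stop_validation("'", path, "': time_s must be finite numbers")
  trains <- split(df$time_s, df$location)
  rows <- split(seq_len(nrow(df)), df$location)
  for (loc in names(trains)) {
    d <- diff(trains[[loc]])
    if (any(d == 0))
      stop_validation("'", path, "': duplicate timestamp at location '", loc,
                      "' (rows ", paste(rows[[loc]][which(d == 0) + 1L] + 1L,
                                        collapse = ", "), ")")
    if (any(d < 0))
      stop_validation("'", path, "': times not increasing at location '", loc,
                      "' (rows ", paste(rows[[loc]][which(d < 0) + 1L] + 1L,
                                        collapse = ", "), ")")
    if (!is.null(refractory_s) && any(d < refractory_s - .refractory_eps))
      stop_validation("'", path, "': refractory separation violated at '", loc,
                      "' (rows ",
                      paste(rows[[loc]][which(d < refractory_s - .refractory_eps) + 1L] + 1L,
                            collapse = ", "), ")")
  }
  trains[order(names(trains))]
}

#' Write a collision log (CSV)
#'
#' @param result A `cap_sim_result`.
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_collisions <- function(result, path) {
  stopifnot(inherits(result, "cap_sim_result"))
  write.csv(result$collisions, path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Records everything needed to re-run a stochastic command
#' bit-identically: fully resolved parameters, seed, tool version,
#' digests of the input files and a timestamp.
#'
#' @param parameters Named list of fully resolved parameters.
#' @param seed Integer seed (or `NULL`).
#' @param input_files Character vector of input paths to digest.
#' @param path File path for `write_manifest()`.
#' @param manifest A manifest list.
#' @return `run_manifest()` returns the manifest list;
#'   `write_manifest()` returns `path` invisibly.
#' @export
run_manifest <- function(parameters = list(), seed = NULL,
                         input_files = character()) {
  digests <- if (length(input_files))
    as.list(tools::md5sum(input_files)) else list()
  list(tool = "capsim",
       version = as.character(packageVersion("capsim")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed,
       parameters = parameters,
       input_digests = digests)
}

#' @rdname run_manifest
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
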