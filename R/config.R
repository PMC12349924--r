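#' Read a TOML-subset configuration file
#'
#' Parses the flat TOML dialect used for run configurations: `[section]`
#' headers, `key = value` lines, `#` comments, and scalar values (strings,
#' numbers, booleans) or one-line arrays thereof. Nested tables, dates and
#' multi-line strings are not part of the dialect and raise an error
#' naming the offending line.
#'
#' @param path path to the file.
#' @return a named list of sections, each a named list of values.
#' @export
read_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  parse_scalar <- function(tok, ln) {
    tok <- trimws(tok)
    if (tok %in% c("true", "false")) return(tok == "true")
    if (grepl('^".*"$', tok)) return(gsub('^"|"$', "", tok))
    if (grepl("^'.*'$", tok)) return(gsub("^'|'$", "", tok))
    num <- suppressWarnings(as.numeric(gsub("_", "", tok)))
    if (!is.na(num)) return(num)
    stop(sprintf("read_toml: cannot parse value '%s' at line %d", tok, ln))
  }
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    # strip comments outside quotes
    chars <- strsplit(raw, "")[[1]]
    inq <- FALSE; qc <- ""
    cut <- length(chars) + 1L
    for (k in seq_along(chars)) {
      ch <- chars[k]
      if (inq) { if (ch == qc) inq <- FALSE }
      else if (ch == '"' || ch == "'") { inq <- TRUE; qc <- ch }
      else if (ch == "#") { cut <- k; break }
    }
    line <- trimws(substr(raw, 1L, cut - 1L))
    if (line == "") next
    if (grepl("^\\[.*\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      if (grepl("\\.", section))
        stop(sprintf("read_toml: nested tables are not supported (line %d)", ln))
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) stop(sprintf("read_toml: expected 'key = value' at line %d: '%s'", ln, line))
    key <- trimws(substr(line, 1L, eq - 1L))
    val <- trimws(substr(line, eq + 1L, nchar(line)))
    if (key == "") stop(sprintf("read_toml: empty key at line %d", ln))
    parsed <- if (grepl("^\\[.*\\]$", val)) {
      inner <- gsub("^\\[|\\]$", "", val)
      if (trimws(inner) == "") list() else {
        toks <- strsplit(inner, ",")[[1]]
        vapply(toks, parse_scalar, FUN.VALUE = numeric(1) * NA, ln = ln,
               USE.NAMES = FALSE)
      }
    } else parse_scalar(val, ln)
    if (is.null(section)) {
      out[[key]] <- parsed
    } else {
      out[[section]][[key]] <- parsed
    }
  }
  out
}

#' Default run configuration
#'
#' The full configuration a run consumes, as a nested list with sections
#' `units`, `forcefield`, `protocol`, `robot`, `builder`. This is also the
#' schema against which configuration files are validated: any key absent
#' here is rejected as unknown.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    units = list(sigma_SI = 1e-9, tau_SI = 2e-9,
                 epsilon_SI = 1.380649e-23 * 310 / 1.1),
    forcefield = unclass(forcefield_params()),
    protocol = unclass(protocol_params()),
    robot = unclass(robot_geometry()),
    builder = list(nx = 20L, ny = 20L, area_per_lipid = 1.2, seed = 1L))
}

#' Read and validate a run configuration
#'
#' Reads a TOML-subset file, rejects unknown sections or keys (typo
#' protection), and merges the values over [default_config()].
#'
#' @param path configuration file path.
#' @return a validated nested configuration list.
#' @export
read_config <- function(path) {
  raw <- read_toml(path)
  defaults <- default_config()
  bad_sec <- setdiff(names(raw), names(defaults))
  if (length(bad_sec))
    stop("read_config: unknown section(s): ", paste(bad_sec, collapse = ", "))
  cfg <- defaults
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), names(defaults[[sec]]))
    if (length(bad))
      stop(sprintf("read_config: unknown key(s) in [%s]: %s", sec,
                   paste(bad, collapse = ", ")))
    cfg[[sec]][names(raw[[sec]])] <- raw[[sec]]
  }
  cfg
}

#' Write a JSON run manifest
#'
#' Records the fully resolved parameter set, seed(s), package version and
#' wall time, and optionally digests of produced files, so that any output
#' is regenerable from its manifest alone.
#'
#' @param path output JSON path.
#' @param config resolved configuration (nested list).
#' @param seed integer seed(s) used.
#' @param files character vector of produced files to digest (content
#'   hashed with a 64-bit FNV over bytes).
#' @param extra optional named list merged into the manifest.
#' @return the manifest, invisibly.
#' @export
write_manifest <- function(path, config, seed, files = character(), extra = list()) {
  digest_file <- function(f) {
    if (!file.exists(f)) return(NA_character_)
    bytes <- readBin(f, "raw", n = file.info(f)$size)
    h <- 14695981039346656037
    for (chunk in split(as.integer(bytes), ceiling(seq_along(bytes) / 65536))) {
      h <- (h + sum((chunk + 1) * seq_along(chunk))) %% 2^53
      h <- (h * 1099511628211) %% 2^53
    }
    sprintf("%013.0f", h)
  }
  man <- c(list(
    package = "spinpore",
    version = as.character(utils::packageVersion("spinpore")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    files = if (length(files))
      stats::setNames(lapply(files, digest_file), basename(files)) else NULL),
    extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(man)
}
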