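# Plain-text batch file grammar:
#   header lines start with '#', one 'key=value' per line; numeric vectors
#   are space-separated, the reactivity matrix is ';'-separated rows;
#   body lines are chains, monomer symbols separated by single spaces.
# Written with 17 significant digits so numeric round trips are exact.

fmt_num <- function(x) paste(sprintf("%.17g", x), collapse = " ")

#' Write a batch to a plain-text sequence file
#'
#' One chain per line (monomer symbols, space-delimited, alpha end first),
#' preceded by `#`-prefixed `key=value` header lines carrying the full
#' system definition, simulation config, seed and pool accounting —
#' everything needed for a lossless round trip via [read_batch()].
#'
#' @param batch an `rhp_batch`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_batch <- function(batch, path) {
  stopifnot(inherits(batch, "rhp_batch"))
  sys <- batch$system
  cfg <- batch$config
  h <- c(
    "format=rhp-batch/1",
    paste0("symbols=", paste(sys$symbols, collapse = " ")),
    paste0("hlb=", fmt_num(sys$hlb)),
    paste0("molecular_weight=", fmt_num(sys$molecular_weight)),
    paste0("density=", fmt_num(sys$density)),
    paste0("feed=", fmt_num(sys$feed)),
    paste0("hlb_threshold=", fmt_num(sys$hlb_threshold)),
    paste0("reactivity=", paste(apply(sys$reactivity, 1, fmt_num),
                                collapse = ";")),
    paste0("protein_derived=", isTRUE(batch$protein_derived))
  )
  for (key in names(cfg)) {
    v <- cfg[[key]]
    if (!is.null(v))
      h <- c(h, paste0("config.", key, "=",
                       if (is.numeric(v)) fmt_num(v) else as.character(v)))
  }
  if (!is.null(batch$initial_pool))
    h <- c(h, paste0("initial_pool=", fmt_num(batch$initial_pool)))
  if (!is.null(batch$consumed))
    h <- c(h, paste0("consumed=", fmt_num(batch$consumed)))
  body <- vapply(batch$chains,
                 function(ch) paste(sys$symbols[ch], collapse = " "),
                 character(1))
  writeLines(c(paste0("# ", h), body), path, useBytes = TRUE)
  invisible(path)
}

parse_nums <- function(x) {
  parts <- strsplit(x, " ", fixed = TRUE)[[1]]
  suppressWarnings(as.numeric(parts))  # "NA" fields parse to NA
}

#' Read a batch from a plain-text sequence file
#'
#' Inverse of [write_batch()]. The monomer system is reconstructed from the
#' header unless one is supplied, in which case body symbols are resolved
#' against it. An unknown symbol is an error naming the symbol and the line.
#'
#' @param path batch file path.
#' @param system optional [monomer_system()] overriding the header system.
#' @return An `rhp_batch`.
#' @export
read_batch <- function(path, system = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_header <- startsWith(lines, "#")
  hdr <- sub("^#\\s*", "", lines[is_header])
  kv <- regmatches(hdr, regexpr("=", hdr), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- setNames(vapply(kv, function(p)
    if (length(p) == 2) p[2] else "", character(1)), keys)

  if (is.null(system)) {
    if (!all(c("symbols", "hlb", "feed") %in% keys))
      stop("header lacks a monomer system (symbols/hlb/feed) and none given")
    symbols <- strsplit(vals[["symbols"]], " ", fixed = TRUE)[[1]]
    rr <- if ("reactivity" %in% keys) {
      rows <- strsplit(vals[["reactivity"]], ";", fixed = TRUE)[[1]]
      do.call(rbind, lapply(rows, parse_nums))
    } else NULL
    system <- monomer_system(
      data.frame(symbol = symbols,
                 hlb = parse_nums(vals[["hlb"]]),
                 molecular_weight = if ("molecular_weight" %in% keys)
                   parse_nums(vals[["molecular_weight"]]) else NA_real_,
                 density = if ("density" %in% keys)
                   parse_nums(vals[["density"]]) else NA_real_,
                 stringsAsFactors = FALSE),
      feed = parse_nums(vals[["feed"]]),
      reactivity = rr,
      hlb_threshold = if ("hlb_threshold" %in% keys)
        parse_nums(vals[["hlb_threshold"]]) else 9)
  }

  body <- lines[!is_header]
  body_lineno <- which(!is_header)
  body_keep <- nzchar(trimws(body))
  body <- body[body_keep]
  body_lineno <- body_lineno[body_keep]
  chains <- vector("list", length(body))
  for (i in seq_along(body)) {
    syms <- strsplit(trimws(body[i]), "\\s+")[[1]]
    idx <- match(syms, system$symbols)
    if (anyNA(idx)) {
      bad <- syms[which(is.na(idx))[1]]
      stop("unknown monomer symbol '", bad, "' on line ", body_lineno[i],
           " of ", path)
    }
    chains[[i]] <- idx
  }

  cfg_keys <- keys[startsWith(keys, "config.")]
  cfg <- lapply(cfg_keys, function(kk) {
    v <- vals[[kk]]
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  })
  names(cfg) <- sub("^config\\.", "", cfg_keys)

  structure(list(
    chains = chains,
    system = system,
    config = cfg,
    initial_pool = if ("initial_pool" %in% keys)
      setNames(parse_nums(vals[["initial_pool"]]), system$symbols) else NULL,
    consumed = if ("consumed" %in% keys)
      setNames(parse_nums(vals[["consumed"]]), system$symbols) else NULL,
    protein_derived = identical(vals[["protein_derived"]], "TRUE")
  ), class = "rhp_batch")
}

#' Write / read a distribution table as CSV
#'
#' Distribution tables (`level`, `class`, `length`, `value`) are written
#' with full-precision numeric formatting so that re-reading reproduces the
#' in-memory values exactly.
#'
#' @param df a distribution data.frame (see [segment_distribution()]).
#' @param path CSV path.
#' @return `write_distribution`: `path` invisibly; `read_distribution`: the
#'   data.frame.
#' @export
write_distribution <- function(df, path) {
  out <- df
  if ("value" %in% names(out)) out$value <- sprintf("%.17g", out$value)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("value" %in% names(df)) df$value <- as.numeric(df$value)
  if ("length" %in% names(df)) df$length <- as.integer(df$length)
  df
}

#' Write motif matches as BED-like text
#'
#' Tab-separated columns `chain`, `start`, `end`, `length` with 0-based
#' half-open coordinates (positions in logs and plots are 1-based).
#'
#' @param matches the `matches` data.frame from [find_specific_segments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  write.table(matches[, c("chain", "start", "end", "length")], path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML configuration with optional blocks `system` (`symbols`, `feed`,
#' `hlb`, `reactivity` as a list of rows, `hlb_threshold`), `simulate`
#' (`nc`, `dp_target`, `conversion`, `pdi_target`, `seed`), `protein`
#' (`fasta`, `segment_length`, `offset`, `residue_map`), `analyze`
#' (`metric`, `window`, `threshold`, `min_dp`, `marker`, `end_gap`) and
#' `recipe` (`mass_scale`, `dp_target`, `conversion`, `cta_mw`,
#' `initiator_mw`, `cta_initiator_ratio`, `monomer_molarity`).
#'
#' @param path YAML file path.
#' @return A named list; a `system` block is converted to a
#'   [monomer_system()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$system)) {
    sb <- cfg$system
    monomers <- if (is.null(sb$hlb)) sb$symbols else
      data.frame(symbol = unlist(sb$symbols), hlb = unlist(sb$hlb),
                 molecular_weight = if (is.null(sb$molecular_weight))
                   NA_real_ else unlist(sb$molecular_weight),
                 density = if (is.null(sb$density)) NA_real_ else
                   unlist(sb$density),
                 stringsAsFactors = FALSE)
    rr <- if (is.null(sb$reactivity)) NULL else
      do.call(rbind, lapply(sb$reactivity, unlist))
    cfg$system <- monomer_system(
      monomers, feed = unlist(sb$feed), reactivity = rr,
      hlb_threshold = if (is.null(sb$hlb_threshold)) 9 else sb$hlb_threshold)
  }
  cfg
}
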