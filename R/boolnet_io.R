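#' @name boolnet_io
#' @title BoolNet-format interchange
#'
#' @description
#' Writers and a reader for the standard BoolNet text format
#' (`targets, factors` header; one `symbol, expression` line per target;
#' operators `&`, `|`, `!`, explicit parentheses, constants `0`/`1`) and
#' the two companion CSV files: the symbol map (`symbol,name`, bijective)
#' and the initial-values file (`symbol,value` with values 0/1). Line
#' endings are LF.
NULL

#' Write a model in BoolNet format
#'
#' Identity self-updates (free inputs) are rendered as `symbol, symbol`;
#' clamped targets as the literal constant `0` or `1`.
#'
#' @param m a `bbm` model.
#' @param path destination file.
#' @return the path, invisibly.
#' @export
write_boolnet <- function(m, path) {
  stopifnot(inherits(m, "bbm"))
  lines <- c("targets, factors",
             vapply(m$targets$symbol, function(sym)
               paste0(sym, ", ", bx_deparse(m$rules[[sym]])), ""))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Write the symbol map
#'
#' Two-column CSV `symbol,name` linking each model symbol to the original
#' state/reaction/input name; the mapping is bijective.
#'
#' @param m a `bbm` model.
#' @param path destination file.
#' @return the path, invisibly.
#' @export
write_symbols <- function(m, path) {
  stopifnot(inherits(m, "bbm"))
  df <- data.frame(symbol = m$targets$symbol, name = m$targets$name,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write an initial-values file
#'
#' Two-column CSV `symbol,value` with one row per target, values 0/1.
#'
#' @param v named logical vector.
#' @param path destination file.
#' @return the path, invisibly.
#' @export
write_initial_values <- function(v, path) {
  df <- data.frame(symbol = names(v), value = as.integer(v),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an initial-values file
#'
#' @param path CSV written by [write_initial_values()].
#' @return named logical vector.
#' @export
read_initial_values <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  v <- df$value != 0
  names(v) <- df$symbol
  v
}

#' Read a BoolNet-format model
#'
#' Reconstructs a simulatable model from a `.boolnet` file, optionally with
#' its symbol map and initial-values companions. Target kinds are taken
#' from the symbol map when available (inputs are names in square
#' brackets); otherwise a target whose rule is an identity self-reference
#' is classed as an input and the rest as states.
#'
#' @param path the `.boolnet` file.
#' @param symbols_path optional symbol-map CSV.
#' @param init_path optional initial-values CSV.
#' @return a `bbm` model. Writing it back with [write_boolnet()]
#'   reproduces the document up to whitespace and redundant parentheses.
#' @export
read_boolnet <- function(path, symbols_path = NULL, init_path = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !grepl("^targets\\s*,\\s*factors$", trimws(lines[1])))
    stop("not a BoolNet file (missing 'targets, factors' header): ", path)
  body <- lines[-1]
  syms <- character(0); rules <- list()
  for (i in seq_along(body)) {
    ln <- body[i]
    cut <- regexpr(",", ln, fixed = TRUE)
    if (cut == -1L)
      stop("line ", i + 1L, ": expected 'symbol, expression'")
    sym <- trimws(substr(ln, 1L, cut - 1L))
    expr <- trimws(substr(ln, cut + 1L, nchar(ln)))
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", sym))
      stop("line ", i + 1L, ": bad symbol '", sym, "'")
    rules[[sym]] <- tryCatch(bx_parse(expr), error = function(e)
      stop("line ", i + 1L, ": ", conditionMessage(e)))
    syms <- c(syms, sym)
  }
  for (sym in syms)
    for (ref in bx_refs(rules[[sym]]))
      if (!ref %in% syms)
        stop("rule for '", sym, "' references unknown target '", ref, "'")

  nm <- syms
  kind <- ifelse(vapply(syms, function(s) {
    r <- rules[[s]]
    r$kind == "ref" && identical(r$sym, s)
  }, TRUE), "input", "state")
  if (!is.null(symbols_path)) {
    sm <- utils::read.csv(symbols_path, stringsAsFactors = FALSE)
    idx <- match(syms, sm$symbol)
    nm <- ifelse(is.na(idx), syms, sm$name[idx])
    kind <- ifelse(grepl("^\\[.*\\]$", nm), "input", kind)
  }
  targets <- data.frame(symbol = syms,
                        kind = as.character(kind),
                        name = as.character(nm),
                        neutral = logical(length(syms)),
                        stringsAsFactors = FALSE)
  m <- structure(list(targets = targets, rules = rules,
                      options = compile_options(),
                      symbol_map = as.list(structure(syms, names = nm))),
                 class = "bbm")
  m$init <- if (!is.null(init_path)) read_initial_values(init_path)[syms]
            else default_initial_state(m)
  m
}
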