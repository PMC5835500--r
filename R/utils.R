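# Shared low-level helpers: item notation, fixed-width window strings,
# half-up rounding, and RNG scoping.

PAD_SYMBOL <- "-"
UNCLASSIFIED_SYMBOL <- "X"

#' The twenty standard one-letter amino-acid codes
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Format a pattern item
#'
#' Items use the angle-bracket notation of the association-mining
#' literature, e.g. `"<L,2>"`: symbol `L` at signed offset +2 relative to
#' the target asparagine (which sits at offset 0).
#'
#' @param symbol single character, a residue letter or a group symbol.
#' @param position signed integer offset; 0 (the target residue itself)
#'   is not a valid item position.
#' @return Item string such as `"<L,2>"`.
#' @export
#' @examples
#' item("L", 2)
#' item("A", -5)
item <- function(symbol, position) {
  stopifnot(is.character(symbol), nchar(symbol) == 1L)
  position <- as.integer(position)
  if (any(position == 0L)) {
    stop("item position 0 is the target residue and cannot be an item")
  }
  sprintf("<%s,%d>", symbol, position)
}

# Parse item strings into a data.frame(symbol, position).
item_fields <- function(items) {
  m <- regmatches(items, regexec("^<([A-Za-z]),(-?[0-9]+)>$", items))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed item(s): ", paste(items[bad], collapse = ", "))
  }
  data.frame(
    symbol = vapply(m, `[[`, character(1), 2L),
    position = as.integer(vapply(m, `[[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
}

#' Split a pattern string into its items
#'
#' @param pattern a pattern string such as `"<O,1><L,2>"`, or an already
#'   split character vector of items.
#' @return Character vector of item strings in canonical order
#'   (by position, then symbol).
#' @export
parse_pattern <- function(pattern) {
  if (length(pattern) == 1L && !grepl("^<[A-Za-z],-?[0-9]+>$", pattern)) {
    pattern <- regmatches(pattern, gregexpr("<[^<>]*>", pattern))[[1]]
  }
  items <- canonical_items(pattern)
  if (any(item_fields(items)$position == 0L)) {
    stop("items at offset 0 (the target residue) are not allowed")
  }
  items
}

# Canonical item order: position ascending, then symbol.
canonical_items <- function(items) {
  items <- unique(items)
  f <- item_fields(items)
  items[order(f$position, f$symbol)]
}

#' Collapse items into a canonical pattern string
#'
#' @param items character vector of item strings.
#' @return Single pattern string, items sorted by position then symbol.
#' @export
pattern_string <- function(items) {
  paste(canonical_items(items), collapse = "")
}

# Flank width implied by a set of window strings (all must share one odd
# length 2*flank+1).
window_flank <- function(windows) {
  len <- unique(nchar(windows))
  if (length(len) != 1L) {
    stop("windows have inconsistent lengths: ", paste(len, collapse = ", "))
  }
  if (len %% 2L != 1L) stop("window length must be odd (2*flank+1)")
  (len - 1L) %/% 2L
}

# Column index (1-based) of a signed offset within a window string.
offset_column <- function(position, flank) {
  col <- position + flank + 1L
  if (any(col < 1L | col > 2L * flank + 1L)) {
    stop("offset(s) outside the window: ",
         paste(position[col < 1L | col > 2L * flank + 1L], collapse = ", "))
  }
  col
}

# One character per cell matrix view of equal-length windows.
window_matrix <- function(windows) {
  len <- unique(nchar(windows))
  stopifnot(length(len) == 1L)
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         ncol = len, byrow = TRUE)
}

# Half-up rounding used for all reported integer percentages.
round_half_up <- function(x) floor(x + 0.5)

# Evaluate code with a locally seeded RNG, restoring global state after.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
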