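# Charge/polarity encoding of residue windows into the five side-chain
# classes P, N, L, O, A (plus the reserved unclassified symbol for Pro).

#' Build the default charge/polarity classification scheme
#'
#' Five side-chain groups cover 19 of the 20 standard residues:
#' \describe{
#'   \item{P}{positively charged: K, R, H}
#'   \item{N}{negatively charged: D, E}
#'   \item{L}{polar, uncharged: S, T, C, M, N, Q}
#'   \item{O}{non-polar, aliphatic: G, A, V, L, I}
#'   \item{A}{aromatic: F, Y, W}
#' }
#' Proline belongs to no group and maps, by default, to the reserved
#' symbol `"X"`, which can never be a mined item; this keeps the omission
#' visible rather than silently folding Pro into the aliphatic class.
#' `proline` reassigns it to one of the five groups if desired.
#'
#' Note the deliberate alphabet split: the group symbol `N` (acidic D/E)
#' is unrelated to the residue letter `N` (asparagine); encoded and raw
#' strings are never mixed.
#'
#' @param proline group symbol to assign proline to (`"P"`, `"N"`, `"L"`,
#'   `"O"`, `"A"`), or `"X"` (default) to leave it unclassified.
#' @return A `glyco_scheme` object.
#' @export
#' @examples
#' sch <- default_scheme()
#' scheme_lookup(sch, c("K", "N", "P"))
default_scheme <- function(proline = UNCLASSIFIED_SYMBOL) {
  groups <- list(
    P = c("K", "R", "H"),
    N = c("D", "E"),
    L = c("S", "T", "C", "M", "N", "Q"),
    O = c("G", "A", "V", "L", "I"),
    A = c("F", "Y", "W")
  )
  if (!identical(proline, UNCLASSIFIED_SYMBOL)) {
    if (!proline %in% names(groups)) {
      stop("proline must be one of ",
           paste(c(names(groups), UNCLASSIFIED_SYMBOL), collapse = ", "))
    }
    groups[[proline]] <- c(groups[[proline]], "P")
  }
  new_scheme(groups, unclassified = UNCLASSIFIED_SYMBOL)
}

# Construct and validate a scheme from a named list of residue groups.
new_scheme <- function(groups, unclassified = UNCLASSIFIED_SYMBOL) {
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("scheme groups overlap on: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  if (!all(members %in% AA_STANDARD)) {
    stop("scheme contains non-standard residue(s): ",
         paste(setdiff(members, AA_STANDARD), collapse = ", "))
  }
  if (unclassified %in% names(groups)) {
    stop("unclassified symbol collides with a group symbol")
  }
  map <- stats::setNames(rep(unclassified, length(AA_STANDARD)),
                         AA_STANDARD)
  for (g in names(groups)) map[groups[[g]]] <- g
  structure(list(groups = groups, unclassified = unclassified, map = map),
            class = "glyco_scheme")
}

#' @export
print.glyco_scheme <- function(x, ...) {
  cat("Charge/polarity classification scheme\n")
  for (g in names(x$groups)) {
    cat(sprintf("  %s: %s\n", g, paste(x$groups[[g]], collapse = ", ")))
  }
  un <- setdiff(AA_STANDARD, unlist(x$groups))
  if (length(un) > 0L) {
    cat(sprintf("  %s (unclassified): %s\n", x$unclassified,
                paste(un, collapse = ", ")))
  }
  invisible(x)
}

#' Look up the group symbol of residues
#'
#' @param scheme a `glyco_scheme`.
#' @param residues character vector of one-letter residue codes.
#' @return Character vector of group symbols (unclassified residues give
#'   the scheme's reserved symbol).
#' @export
scheme_lookup <- function(scheme, residues) {
  stopifnot(inherits(scheme, "glyco_scheme"))
  unknown <- setdiff(residues, names(scheme$map))
  if (length(unknown) > 0L) {
    stop("residue(s) outside the scheme: ", paste(unknown, collapse = ", "))
  }
  unname(scheme$map[residues])
}

#' Encode windows into group symbols
#'
#' Position-wise substitution of residue letters by their group symbol;
#' terminal pads (`"-"`) are preserved. The centre asparagine encodes to
#' `L` (polar, uncharged).
#'
#' @param windows character vector of residue windows.
#' @param scheme a `glyco_scheme` (default [default_scheme()]).
#' @return Character vector of encoded windows, same lengths.
#' @export
#' @examples
#' encode_window("NVSR")   # "LOLP"
encode_window <- function(windows, scheme = default_scheme()) {
  stopifnot(inherits(scheme, "glyco_scheme"))
  ok <- paste0(c(names(scheme$map), PAD_SYMBOL), collapse = "")
  bad <- grepl(paste0("[^", ok, "]"), windows)
  if (any(bad)) {
    stop("window(s) contain characters outside the scheme: ",
         paste(utils::head(windows[bad], 3L), collapse = ", "))
  }
  chartr(paste(names(scheme$map), collapse = ""),
         paste(scheme$map, collapse = ""),
         windows)
}

#' Encode the windows of a site table
#'
#' @param windows_df data.frame with a `window` column (see
#'   [extract_windows()]).
#' @param scheme a `glyco_scheme`.
#' @return The data.frame with an added `encoded` column.
#' @export
encode_windows <- function(windows_df, scheme = default_scheme()) {
  stopifnot("window" %in% names(windows_df))
  windows_df$encoded <- encode_window(windows_df$window, scheme)
  windows_df
}

#' Serialise a scheme to JSON
#'
#' Written as `{"P": "KRH", ..., "unclassified": "X"}`.
#'
#' @param scheme a `glyco_scheme`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scheme_json <- function(scheme, path) {
  stopifnot(inherits(scheme, "glyco_scheme"))
  obj <- c(lapply(scheme$groups, paste, collapse = ""),
           list(unclassified = scheme$unclassified))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a scheme from JSON
#'
#' @param path path to a scheme JSON file (see [write_scheme_json()]).
#' @return A `glyco_scheme`.
#' @export
read_scheme_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unclassified <- obj[["unclassified"]] %||% UNCLASSIFIED_SYMBOL
  groups <- obj[setdiff(names(obj), "unclassified")]
  new_scheme(lapply(groups, function(g) strsplit(g, "")[[1]]),
             unclassified = unclassified)
}
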