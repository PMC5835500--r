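# Position-specific composition statistics and the exact binomial
# preference test that defines which (symbol, position) items are
# eligible for association mining.

#' Position-specific frequency matrix
#'
#' Per-position symbol fractions over the non-pad occupancy of each
#' position. Works on raw residue windows and on encoded windows alike.
#'
#' @param windows character vector of equal-length windows.
#' @return A `glyco_pfm` object: list with `counts` and `freq` matrices
#'   (symbols x positions), `occupancy` (non-pad count per position),
#'   `positions` (signed offsets), `n_windows` and `flank`.
#' @export
position_frequency_matrix <- function(windows) {
  if (length(windows) == 0L) stop("no windows supplied")
  flank <- window_flank(windows)
  m <- window_matrix(windows)
  symbols <- sort(setdiff(unique(as.vector(m)), PAD_SYMBOL))
  counts <- vapply(
    seq_len(ncol(m)),
    function(j) as.integer(table(factor(m[, j], levels = symbols))),
    integer(length(symbols))
  )
  counts <- matrix(counts, nrow = length(symbols),
                   dimnames = list(symbols, as.character(-flank:flank)))
  occupancy <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(occupancy, 1L), "/")
  structure(
    list(counts = counts, freq = freq, occupancy = occupancy,
         positions = -flank:flank, n_windows = length(windows),
         flank = flank),
    class = "glyco_pfm"
  )
}

#' @export
print.glyco_pfm <- function(x, ...) {
  cat(sprintf("Position frequency matrix: %d windows, offsets %d..%d, %d symbols\n",
              x$n_windows, -x$flank, x$flank, nrow(x$counts)))
  invisible(x)
}

#' Export a PFM as a logo-style matrix
#'
#' Positions in rows, symbols in columns -- the orientation expected by
#' standard sequence-logo plotting inputs.
#'
#' @param pfm a `glyco_pfm`.
#' @return Numeric matrix (positions x symbols) of frequencies.
#' @export
logo_matrix <- function(pfm) {
  stopifnot(inherits(pfm, "glyco_pfm"))
  t(pfm$freq)
}

#' Pooled background symbol composition
#'
#' Symbol fractions pooled over all window positions except the centre
#' (offset 0, which is the invariant asparagine) and terminal pads.
#'
#' @param windows character vector of equal-length windows.
#' @return Named numeric vector of fractions summing to 1.
#' @export
background_composition <- function(windows) {
  if (length(windows) == 0L) stop("no windows supplied")
  flank <- window_flank(windows)
  m <- window_matrix(windows)[, -(flank + 1L), drop = FALSE]
  v <- as.vector(m)
  v <- v[v != PAD_SYMBOL]
  if (length(v) == 0L) stop("windows contain no non-pad flanking symbols")
  tab <- table(v)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Significantly preferred (symbol, position) items
#'
#' For every symbol and non-zero offset, the observed count at that
#' offset is tested against the pooled background composition with a
#' one-sided exact binomial test (enrichment only; depletion is never
#' "preferred"). The number of trials at an offset is its non-pad
#' occupancy, so terminal pads dilute nothing. Offset 0 is excluded (it
#' is 'N' by construction), as are pad and unclassified symbols, which
#' can never become items.
#'
#' No multiple-testing correction is applied by default, mimicking the
#' permissive behaviour of classical PTM-context preference tables;
#' Benjamini-Hochberg is available via `correction = "BH"`.
#'
#' @param windows character vector of windows from a single class.
#' @param alpha significance level (default 0.05).
#' @param correction `"none"` (default) or `"BH"`.
#' @param background optional named fraction vector overriding the pooled
#'   composition of `windows` (e.g. to share one background across
#'   classes).
#' @param class_label optional label (`"N+"` / `"N-"`) stored on the
#'   result.
#' @return A `preference_table` data.frame: `symbol`, `position`, `count`,
#'   `n`, `observed_freq`, `background_freq`, `p_value`, `p_adjusted`,
#'   `preferred`, `item`.
#' @export
preferred_items <- function(windows, alpha = 0.05,
                            correction = c("none", "BH"),
                            background = NULL, class_label = NULL) {
  correction <- match.arg(correction)
  if (length(windows) < 10L) {
    warning("only ", length(windows),
            " windows: the preference test is underpowered")
  }
  pfm <- position_frequency_matrix(windows)
  bg <- background %||% background_composition(windows)

  symbols <- setdiff(rownames(pfm$counts),
                     c(PAD_SYMBOL, UNCLASSIFIED_SYMBOL))
  positions <- setdiff(pfm$positions, 0L)
  grid <- expand.grid(symbol = symbols, position = positions,
                      stringsAsFactors = FALSE)
  col <- match(as.character(grid$position), colnames(pfm$counts))
  x <- pfm$counts[cbind(match(grid$symbol, rownames(pfm$counts)), col)]
  n <- pfm$occupancy[col]
  p0 <- ifelse(grid$symbol %in% names(bg), bg[grid$symbol], 0)

  # Exact one-sided binomial tail P(X >= x | n, p0).
  p_value <- stats::pbinom(x - 1L, n, p0, lower.tail = FALSE)
  p_adjusted <- if (correction == "BH") stats::p.adjust(p_value, "BH")
                else p_value
  observed <- ifelse(n > 0L, x / n, 0)
  out <- data.frame(
    symbol = grid$symbol, position = grid$position,
    count = as.integer(x), n = as.integer(n),
    observed_freq = observed, background_freq = as.numeric(p0),
    p_value = p_value, p_adjusted = p_adjusted,
    preferred = n > 0L & observed > p0 & p_adjusted < alpha,
    stringsAsFactors = FALSE
  )
  out$item <- item(out$symbol, out$position)
  out <- out[order(out$position, out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("preference_table", "data.frame"),
            alpha = alpha, correction = correction,
            class_label = class_label, n_windows = length(windows))
}

#' @export
print.preference_table <- function(x, ...) {
  lab <- attr(x, "class_label")
  cat(sprintf("Preference table%s: %d tests, %d preferred (alpha = %g, correction = %s)\n",
              if (is.null(lab)) "" else paste0(" [", lab, "]"),
              nrow(x), sum(x$preferred), attr(x, "alpha"),
              attr(x, "correction")))
  pref <- x[x$preferred, , drop = FALSE]
  if (nrow(pref) > 0L) {
    print.data.frame(utils::head(
      pref[order(pref$p_value),
           c("item", "count", "n", "observed_freq", "background_freq",
             "p_value")], 20L))
  }
  invisible(x)
}

#' Items eligible for mining
#'
#' @param preference a `preference_table`.
#' @return Character vector of the preferred items, canonical order.
#' @export
eligible_items <- function(preference) {
  stopifnot(inherits(preference, "preference_table"))
  items <- preference$item[preference$preferred]
  if (length(items) == 0L) character(0) else canonical_items(items)
}

#' Write a preference table as TSV
#'
#' @param preference a `preference_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_preference_tsv <- function(preference, path) {
  utils::write.table(as.data.frame(preference), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
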