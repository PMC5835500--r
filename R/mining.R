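# Association-pattern mining over preferred (symbol, position) items:
# supports on the consequent-class windows, Apriori enumeration with an
# optional maximal-only filter, confidence on the balanced two-class set,
# and a support-grid sweep with deduplication.

# Logical matrix (windows x items): does window w carry item i?
# Pad and unclassified symbols never match.
item_match_matrix <- function(windows, items, flank = window_flank(windows)) {
  f <- item_fields(items)
  cols <- offset_column(f$position, flank)
  out <- vapply(seq_along(items), function(i) {
    if (f$symbol[i] %in% c(PAD_SYMBOL, UNCLASSIFIED_SYMBOL)) {
      rep(FALSE, length(windows))
    } else {
      substr(windows, cols[i], cols[i]) == f$symbol[i]
    }
  }, logical(length(windows)))
  matrix(out, nrow = length(windows), dimnames = list(NULL, items))
}

#' Does each window carry a full pattern?
#'
#' True iff every item's symbol equals the window symbol at that offset.
#' Pads (`"-"`) and the unclassified symbol match nothing. The caller is
#' responsible for matching alphabets (raw rules against raw windows,
#' encoded against encoded); see [conformity_report()] for a checked
#' interface.
#'
#' @param windows character vector of windows (raw or encoded).
#' @param items pattern: item character vector or pattern string.
#' @return Logical vector, one element per window.
#' @export
rule_matches <- function(windows, items) {
  items <- parse_pattern(items)
  if (length(items) == 0L) stop("pattern has no items")
  m <- item_match_matrix(windows, items)
  rowSums(m) == length(items)
}

#' Support of a pattern
#'
#' Percentage of consequent-class windows containing every item of the
#' pattern at its offset.
#'
#' @param items pattern items (character vector or pattern string).
#' @param class_windows windows of the consequent class.
#' @return Support percentage in `[0, 100]`.
#' @export
pattern_support <- function(items, class_windows) {
  if (length(class_windows) == 0L) stop("no class windows supplied")
  100 * mean(rule_matches(class_windows, items))
}

#' Confidence of a pattern for its consequent class
#'
#' Among all windows of the balanced two-class set containing the
#' pattern, the percentage that belong to the consequent class.
#'
#' @param items pattern items.
#' @param consequent_windows windows of the consequent class.
#' @param other_windows windows of the other class (balanced).
#' @return Confidence percentage in `(0, 100]`.
#' @export
pattern_confidence <- function(items, consequent_windows, other_windows) {
  m_cons <- sum(rule_matches(consequent_windows, items))
  m_other <- sum(rule_matches(other_windows, items))
  if (m_cons + m_other == 0L) {
    stop("pattern ", pattern_string(parse_pattern(items)),
         " matches no window in either class; confidence undefined")
  }
  100 * m_cons / (m_cons + m_other)
}

# Level-wise Apriori over the item match matrix. Returns all frequent
# itemsets as a list of integer index vectors with their supports.
apriori_frequent <- function(match_matrix, min_support_pct) {
  n <- nrow(match_matrix)
  if (n == 0L) stop("no windows supplied")
  thr <- min_support_pct - 1e-9
  sup1 <- 100 * colMeans(match_matrix)
  keep <- which(sup1 >= thr)
  sets <- lapply(keep, function(i) list(idx = i,
                                        match = match_matrix[, i],
                                        support = sup1[i]))
  frequent <- sets
  level <- sets
  while (length(level) >= 2L) {
    keys <- vapply(level, function(s) paste(s$idx, collapse = ","),
                   character(1))
    freq_keys <- vapply(frequent, function(s) paste(s$idx, collapse = ","),
                        character(1))
    nxt <- list()
    seen <- character(0)
    for (a in seq_along(level)) {
      for (b in seq_along(level)) {
        if (b <= a) next
        u <- sort(union(level[[a]]$idx, level[[b]]$idx))
        if (length(u) != length(level[[a]]$idx) + 1L) next
        key <- paste(u, collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        # Downward-closure pruning: every (k-1)-subset must be frequent.
        subs_ok <- all(vapply(seq_along(u), function(d) {
          paste(u[-d], collapse = ",") %in% freq_keys
        }, logical(1)))
        if (!subs_ok) next
        match <- rowSums(match_matrix[, u, drop = FALSE]) == length(u)
        support <- 100 * mean(match)
        if (support >= thr) {
          nxt[[length(nxt) + 1L]] <- list(idx = u, match = match,
                                          support = support)
        }
      }
    }
    frequent <- c(frequent, nxt)
    level <- nxt
  }
  frequent
}

# Keep only itemsets with no frequent proper superset.
filter_maximal <- function(frequent) {
  if (length(frequent) <= 1L) return(frequent)
  keep <- vapply(seq_along(frequent), function(i) {
    !any(vapply(seq_along(frequent), function(j) {
      j != i &&
        length(frequent[[j]]$idx) > length(frequent[[i]]$idx) &&
        all(frequent[[i]]$idx %in% frequent[[j]]$idx)
    }, logical(1)))
  }, logical(1))
  frequent[keep]
}

#' Frequent (maximal) itemsets at one support threshold
#'
#' Apriori enumeration of all itemsets of eligible items whose support in
#' the class windows meets the threshold, optionally filtered to maximal
#' ones (no frequent proper superset).
#'
#' @param items eligible items (from [eligible_items()]).
#' @param class_windows windows of the consequent class.
#' @param min_support_pct support threshold in `(0, 100]`.
#' @param maximal_only keep only maximal itemsets (default `TRUE`).
#' @return data.frame `pattern`, `items` (list-column), `support_pct`,
#'   sorted by support descending then pattern.
#' @export
frequent_maximal_itemsets <- function(items, class_windows,
                                      min_support_pct,
                                      maximal_only = TRUE) {
  items <- canonical_items(items)
  empty <- data.frame(pattern = character(0), support_pct = numeric(0),
                      stringsAsFactors = FALSE)
  empty$items <- list()
  if (length(items) == 0L) return(empty[, c("pattern", "items", "support_pct")])
  m <- item_match_matrix(class_windows, items)
  frequent <- apriori_frequent(m, min_support_pct)
  if (maximal_only) frequent <- filter_maximal(frequent)
  if (length(frequent) == 0L) {
    return(empty[, c("pattern", "items", "support_pct")])
  }
  out <- data.frame(
    pattern = vapply(frequent,
                     function(s) pattern_string(items[s$idx]), character(1)),
    support_pct = vapply(frequent, `[[`, numeric(1), "support"),
    stringsAsFactors = FALSE
  )
  out$items <- lapply(frequent, function(s) canonical_items(items[s$idx]))
  out <- out[order(-out$support_pct, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("pattern", "items", "support_pct")]
}

#' Sweep the support grid and assemble association rules
#'
#' At every threshold of the grid the (maximal) frequent itemsets are
#' mined; itemsets recurring at several thresholds are merged, keeping
#' the set of thresholds where each was emitted. Confidence is computed
#' once per unique itemset on the balanced two-class windows. Both the
#' total number of emitted patterns (with repetitions across the grid)
#' and the number of unique patterns are recorded as attributes
#' `n_emitted` / `n_unique`.
#'
#' @param items eligible items for the consequent class.
#' @param consequent_windows windows of the consequent class.
#' @param other_windows balanced windows of the other class.
#' @param grid support thresholds, ascending, in `(0, 100]`
#'   (default `seq(5, 95, by = 5)`).
#' @param maximal_only maximal-only reporting per threshold (default
#'   `TRUE`); `FALSE` emits all frequent itemsets.
#' @param consequent class label stored on the rules (default `"N+"`).
#' @return An `association_rules` data.frame: `pattern`, `items`
#'   (list-column), `consequent`, `support_pct`, `confidence_pct`,
#'   `thresholds` (list-column).
#' @export
sweep_support_grid <- function(items, consequent_windows, other_windows,
                               grid = seq(5, 95, by = 5),
                               maximal_only = TRUE, consequent = "N+") {
  if (is.unsorted(grid, strictly = TRUE) ||
      any(grid <= 0) || any(grid > 100)) {
    stop("support grid must be strictly ascending within (0, 100]")
  }
  emitted <- lapply(grid, function(thr) {
    sets <- frequent_maximal_itemsets(items, consequent_windows, thr,
                                      maximal_only = maximal_only)
    if (nrow(sets) == 0L) return(NULL)
    sets$threshold <- thr
    sets
  })
  emitted <- do.call(rbind, emitted)
  if (is.null(emitted) || nrow(emitted) == 0L) {
    rules <- data.frame(pattern = character(0), consequent = character(0),
                        support_pct = numeric(0),
                        confidence_pct = numeric(0),
                        stringsAsFactors = FALSE)
    rules$items <- list()
    rules$thresholds <- list()
    rules <- rules[, c("pattern", "items", "consequent", "support_pct",
                       "confidence_pct", "thresholds")]
    return(structure(rules, class = c("association_rules", "data.frame"),
                     n_emitted = 0L, n_unique = 0L))
  }
  patterns <- unique(emitted$pattern)
  rows <- lapply(patterns, function(p) {
    sub <- emitted[emitted$pattern == p, , drop = FALSE]
    data.frame(pattern = p,
               consequent = consequent,
               support_pct = sub$support_pct[1],
               confidence_pct = pattern_confidence(
                 sub$items[[1]], consequent_windows, other_windows),
               stringsAsFactors = FALSE)
  })
  rules <- do.call(rbind, rows)
  rules$items <- lapply(patterns, function(p) {
    emitted$items[emitted$pattern == p][[1]]
  })
  rules$thresholds <- lapply(patterns, function(p) {
    sort(unique(emitted$threshold[emitted$pattern == p]))
  })
  rules <- rules[order(-vapply(rules$thresholds, max, numeric(1)),
                       rules$pattern), , drop = FALSE]
  rownames(rules) <- NULL
  rules <- rules[, c("pattern", "items", "consequent", "support_pct",
                     "confidence_pct", "thresholds")]
  structure(rules, class = c("association_rules", "data.frame"),
            n_emitted = nrow(emitted), n_unique = length(patterns))
}

#' Merge duplicate rules across support thresholds
#'
#' Rules with identical itemset and consequent are merged into one, with
#' their threshold sets unioned. Idempotent.
#'
#' @param rules an `association_rules` data.frame.
#' @return Deduplicated `association_rules`.
#' @export
dedupe_rules <- function(rules) {
  if (nrow(rules) == 0L) return(rules)
  key <- paste(rules$pattern, rules$consequent, sep = "\r")
  groups <- split(seq_len(nrow(rules)), key)
  idx <- vapply(groups, `[[`, integer(1), 1L)
  out <- rules[idx, , drop = FALSE]
  out$thresholds <- lapply(groups, function(g) {
    sort(unique(unlist(rules$thresholds[g])))
  })
  out <- out[order(-vapply(out$thresholds, max, numeric(1)), out$pattern),
             , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("association_rules", "data.frame"),
            n_emitted = attr(rules, "n_emitted"),
            n_unique = nrow(out))
}

#' @export
print.association_rules <- function(x, ...) {
  cat(sprintf("Association rules: %d unique pattern(s)", nrow(x)))
  if (!is.null(attr(x, "n_emitted"))) {
    cat(sprintf(" (%d emitted across the grid)", attr(x, "n_emitted")))
  }
  cat("\n")
  if (nrow(x) > 0L) {
    show <- data.frame(pattern = x$pattern, consequent = x$consequent,
                       support_pct = round(x$support_pct, 2),
                       confidence_pct = round(x$confidence_pct, 2),
                       thresholds = vapply(x$thresholds, paste,
                                           character(1), collapse = ","),
                       stringsAsFactors = FALSE)
    print.data.frame(show)
  }
  invisible(x)
}

#' Build a rule set from pattern strings
#'
#' Convenience constructor for externally specified rule sets (e.g. a
#' published table of patterns) so they can be fed to the validation
#' functions.
#'
#' @param patterns character vector of pattern strings like
#'   `"<O,1><L,2>"`.
#' @param consequent class label (default `"N+"`).
#' @param support_pct,confidence_pct optional numeric annotations.
#' @param thresholds optional list of threshold vectors.
#' @return An `association_rules` data.frame.
#' @export
rules_from_patterns <- function(patterns, consequent = "N+",
                                support_pct = NA_real_,
                                confidence_pct = NA_real_,
                                thresholds = NULL) {
  if (length(patterns) == 0L) {
    rules <- data.frame(pattern = character(0), consequent = character(0),
                        support_pct = numeric(0),
                        confidence_pct = numeric(0),
                        stringsAsFactors = FALSE)
    rules$items <- list()
    rules$thresholds <- list()
    rules <- rules[, c("pattern", "items", "consequent", "support_pct",
                       "confidence_pct", "thresholds")]
    return(structure(rules, class = c("association_rules", "data.frame")))
  }
  items <- lapply(patterns, parse_pattern)
  rules <- data.frame(
    pattern = vapply(items, pattern_string, character(1)),
    consequent = consequent,
    support_pct = support_pct,
    confidence_pct = confidence_pct,
    stringsAsFactors = FALSE
  )
  rules$items <- items
  rules$thresholds <- thresholds %||% rep(list(numeric(0)), length(patterns))
  rules <- rules[, c("pattern", "items", "consequent", "support_pct",
                     "confidence_pct", "thresholds")]
  structure(rules, class = c("association_rules", "data.frame"))
}

#' Write rules as JSON
#'
#' Each rule becomes
#' `{"items": [["L", 2], ...], "consequent": "...", "support_pct": ...,
#' "confidence_pct": ..., "thresholds": [...]}`.
#'
#' @param rules an `association_rules` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rules_json <- function(rules, path) {
  obj <- lapply(seq_len(nrow(rules)), function(i) {
    f <- item_fields(rules$items[[i]])
    list(items = lapply(seq_len(nrow(f)),
                        function(j) list(f$symbol[j], f$position[j])),
         consequent = rules$consequent[i],
         support_pct = rules$support_pct[i],
         confidence_pct = rules$confidence_pct[i],
         thresholds = rules$thresholds[[i]])
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read rules from JSON
#'
#' @param path path written by [write_rules_json()].
#' @return An `association_rules` data.frame.
#' @export
read_rules_json <- function(path) {
  obj <- jsonlite::read_json(path)
  patterns <- vapply(obj, function(r) {
    pattern_string(vapply(r$items, function(it) {
      item(it[[1]], it[[2]])
    }, character(1)))
  }, character(1))
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  rules_from_patterns(
    patterns,
    consequent = vapply(obj, function(r) r$consequent %||% "N+",
                        character(1)),
    support_pct = vapply(obj, function(r) num_or_na(r$support_pct),
                         numeric(1)),
    confidence_pct = vapply(obj, function(r) num_or_na(r$confidence_pct),
                            numeric(1)),
    thresholds = lapply(obj, function(r) {
      as.numeric(unlist(r$thresholds))
    })
  )
}

#' Write rules as a flat TSV
#'
#' Columns `pattern`, `consequent`, `support_pct`, `confidence_pct`,
#' `thresholds` (comma-joined) -- the layout of a published
#' pattern/confidence/support table.
#'
#' @param rules an `association_rules` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rules_tsv <- function(rules, path) {
  flat <- data.frame(
    pattern = rules$pattern,
    consequent = rules$consequent,
    support_pct = rules$support_pct,
    confidence_pct = rules$confidence_pct,
    thresholds = vapply(rules$thresholds, paste, character(1),
                        collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read rules from a flat TSV
#'
#' @param path path written by [write_rules_tsv()] (or a hand-prepared
#'   table in the same layout; `support_pct`/`confidence_pct` may be
#'   absent).
#' @return An `association_rules` data.frame.
#' @export
read_rules_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"pattern" %in% names(tab)) {
    stop("rules TSV '", path, "' lacks a 'pattern' column")
  }
  thresholds <- if ("thresholds" %in% names(tab)) {
    lapply(strsplit(as.character(tab$thresholds), ","),
           function(x) as.numeric(x[nzchar(x)]))
  } else NULL
  rules_from_patterns(
    tab$pattern,
    consequent = if ("consequent" %in% names(tab)) tab$consequent else "N+",
    support_pct = if ("support_pct" %in% names(tab))
      as.numeric(tab$support_pct) else NA_real_,
    confidence_pct = if ("confidence_pct" %in% names(tab))
      as.numeric(tab$confidence_pct) else NA_real_,
    thresholds = thresholds
  )
}
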