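# Independent brute-force oracles for the mining functions. These scan
# windows character by character and enumerate every possible itemset
# explicitly; they share no code path with the Apriori miner.

oracle_item_in_window <- function(window, symbol, position, flank) {
  ch <- substr(window, position + flank + 1L, position + flank + 1L)
  ch == symbol && !(symbol %in% c("-", "X"))
}

oracle_pattern_in_window <- function(window, items, flank) {
  f <- glycoctx:::item_fields(items)
  for (j in seq_len(nrow(f))) {
    if (!oracle_item_in_window(window, f$symbol[j], f$position[j], flank)) {
      return(FALSE)
    }
  }
  TRUE
}

oracle_support <- function(items, windows) {
  flank <- (nchar(windows[1]) - 1L) %/% 2L
  hits <- 0L
  for (w in windows) {
    if (oracle_pattern_in_window(w, items, flank)) hits <- hits + 1L
  }
  100 * hits / length(windows)
}

oracle_confidence <- function(items, pos_windows, neg_windows) {
  flank <- (nchar(pos_windows[1]) - 1L) %/% 2L
  mp <- sum(vapply(pos_windows, oracle_pattern_in_window, logical(1),
                   items = items, flank = flank))
  mn <- sum(vapply(neg_windows, oracle_pattern_in_window, logical(1),
                   items = items, flank = flank))
  100 * mp / (mp + mn)
}

# Exhaustive enumeration of every non-empty subset of the items,
# with maximality applied over the frequent collection.
oracle_itemsets <- function(items, windows, min_support_pct,
                            maximal_only = TRUE) {
  k <- length(items)
  frequent <- list()
  for (size in seq_len(k)) {
    combos <- utils::combn(k, size, simplify = FALSE)
    for (idx in combos) {
      sup <- oracle_support(items[idx], windows)
      if (sup >= min_support_pct - 1e-9) {
        frequent[[length(frequent) + 1L]] <- list(idx = idx, support = sup)
      }
    }
  }
  if (maximal_only && length(frequent) > 1L) {
    keep <- vapply(seq_along(frequent), function(i) {
      !any(vapply(seq_along(frequent), function(j) {
        j != i &&
          length(frequent[[j]]$idx) > length(frequent[[i]]$idx) &&
          all(frequent[[i]]$idx %in% frequent[[j]]$idx)
      }, logical(1)))
    }, logical(1))
    frequent <- frequent[keep]
  }
  if (length(frequent) == 0L) {
    return(data.frame(pattern = character(0), support_pct = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    pattern = vapply(frequent,
                     function(s) pattern_string(items[s$idx]), character(1)),
    support_pct = vapply(frequent, `[[`, numeric(1), "support"),
    stringsAsFactors = FALSE
  )
  out[order(out$pattern), , drop = FALSE]
}

# A random small mining instance: alphabet <= 6 symbols, window length
# <= 7, <= 50 windows, a handful of candidate items.
random_instance <- function(seed) {
  set.seed(seed)
  flank <- sample(1:3, 1)
  n_sym <- sample(2:6, 1)
  symbols <- sample(c("a", "b", "c", "d", "e", "f"), n_sym)
  n <- sample(5:50, 1)
  windows <- vapply(seq_len(n), function(i) {
    paste(sample(symbols, 2 * flank + 1, replace = TRUE), collapse = "")
  }, character(1))
  positions <- setdiff(-flank:flank, 0L)
  combos <- expand.grid(symbol = symbols, position = positions,
                        stringsAsFactors = FALSE)
  pick <- combos[sample(nrow(combos), min(sample(2:6, 1), nrow(combos))), ]
  items <- canonical_items(item(pick$symbol, pick$position))
  list(windows = windows, items = items, flank = flank,
       min_support = sample(c(5, 10, 20, 30, 50, 75), 1))
}
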