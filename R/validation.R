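# Rule validation: conformity percentages on peptide sets, sequon
# classification, and matching of printed motif tables after
# charge/polarity encoding.

#' Integer conformity percentage
#'
#' Percentages are rounded half-up to the nearest integer, the convention
#' used throughout the reported validation tables.
#'
#' @param n_matched number of peptides matching at least one rule.
#' @param n_total total number of peptides.
#' @return Integer percentage.
#' @export
#' @examples
#' conformity_percentage(216, 229)  # 94
conformity_percentage <- function(n_matched, n_total) {
  stopifnot(n_total > 0, n_matched >= 0, n_matched <= n_total)
  as.integer(round_half_up(100 * n_matched / n_total))
}

#' Conformity of a peptide set with a rule set
#'
#' A peptide conforms when it contains at least one of the rules'
#' patterns. The report carries matched/total counts, the integer
#' percentage, and per-rule match counts.
#'
#' @param windows character vector of windows (raw or encoded -- must be
#'   on the same alphabet as the rules).
#' @param rules an `association_rules` data.frame, or a character vector
#'   of pattern strings.
#' @param name dataset name carried in the report.
#' @param alphabet optional declared alphabet of `windows` (`"raw"` or
#'   `"encoded"`); when both this and the rules' `alphabet` attribute are
#'   set, a mismatch is an error.
#' @return A `conformity_report`: list with `dataset_name`, `n_total`,
#'   `n_matched`, `percentage`, `per_rule_counts`.
#' @export
conformity_report <- function(windows, rules, name = "dataset",
                              alphabet = NULL) {
  if (length(windows) == 0L) stop("no windows supplied")
  if (is.character(rules)) rules <- rules_from_patterns(rules)
  rules_alpha <- attr(rules, "alphabet")
  if (!is.null(alphabet) && !is.null(rules_alpha) &&
      !identical(alphabet, rules_alpha)) {
    stop("alphabet mismatch: windows are '", alphabet,
         "' but rules are '", rules_alpha, "'")
  }
  if (nrow(rules) == 0L) {
    per_rule <- integer(0)
    matched <- rep(FALSE, length(windows))
  } else {
    hits <- vapply(rules$items, function(it) rule_matches(windows, it),
                   logical(length(windows)))
    hits <- matrix(hits, nrow = length(windows),
                   dimnames = list(NULL, rules$pattern))
    matched <- rowSums(hits) > 0L
    per_rule <- colSums(hits)
  }
  structure(
    list(dataset_name = name,
         n_total = length(windows),
         n_matched = sum(matched),
         percentage = conformity_percentage(sum(matched), length(windows)),
         per_rule_counts = per_rule),
    class = "conformity_report"
  )
}

#' @export
print.conformity_report <- function(x, ...) {
  cat(sprintf("Conformity [%s]: %d / %d peptides match >=1 rule (%d%%)\n",
              x$dataset_name, x$n_matched, x$n_total, x$percentage))
  invisible(x)
}

#' @export
as.data.frame.conformity_report <- function(x, ...) {
  data.frame(dataset_name = x$dataset_name, n_total = x$n_total,
             n_matched = x$n_matched, percentage = x$percentage,
             stringsAsFactors = FALSE)
}

#' Classify the sequon of each window
#'
#' The sequon class is determined solely by the residue two positions
#' downstream of the asparagine: S gives NXS, T gives NXT, C gives NXC,
#' anything else (including a terminal pad) is non-canonical. The
#' `x_is_proline` flag records whether the +1 position -- the sequon's
#' "X" -- is proline, which disfavours glycosylation.
#'
#' Input may be full windows (odd length, Asn at the centre) or bare
#' sequon strings starting with N (e.g. `"NSTY"`).
#'
#' @param windows character vector of windows or sequon strings (raw
#'   residue alphabet).
#' @return data.frame `window`, `class`
#'   (`"NXS"`/`"NXT"`/`"NXC"`/`"non-canonical"`), `x_is_proline`.
#' @export
#' @examples
#' classify_sequon(c("NSTY", "NNCE", "NYDL"))
classify_sequon <- function(windows) {
  centre <- vapply(windows, function(w) {
    n <- nchar(w)
    mid <- (n + 1L) %/% 2L
    if (n %% 2L == 1L && n >= 5L && substr(w, mid, mid) == "N") {
      mid
    } else if (substr(w, 1L, 1L) == "N") {
      1L
    } else {
      stop("cannot locate the target asparagine in '", w,
           "': not an odd window centred on N, nor a sequon starting ",
           "with N")
    }
  }, integer(1), USE.NAMES = FALSE)
  plus1 <- substr(windows, centre + 1L, centre + 1L)
  plus2 <- substr(windows, centre + 2L, centre + 2L)
  cls <- ifelse(plus2 == "S", "NXS",
         ifelse(plus2 == "T", "NXT",
         ifelse(plus2 == "C", "NXC", "non-canonical")))
  data.frame(window = windows, class = cls,
             x_is_proline = plus1 == "P",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a motif table
#'
#' TSV with columns `protein`, `site` (e.g. `N558`) and `sequon` (a
#' short motif string starting with N, the asparagine at offset 0).
#'
#' @param path path to the TSV.
#' @return data.frame `protein`, `site`, `sequon`.
#' @export
read_motif_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  required <- c("protein", "site", "sequon")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("motif table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  tab[, required]
}

#' Validate a motif table against encoded rules
#'
#' Each printed sequon (offsets 0..len-1 downstream of the asparagine)
#' is embedded in an otherwise-pad window, encoded with the
#' charge/polarity scheme, and matched against the rules. Rules using
#' offsets outside the sequon (upstream items, or downstream beyond its
#' end) cannot be evaluated on such short motifs; they are skipped and
#' reported in `skipped_patterns`.
#'
#' @param entries motif data.frame (`protein`, `site`, `sequon`), e.g.
#'   from [read_motif_table()].
#' @param rules encoded-alphabet rules (`association_rules` or pattern
#'   strings).
#' @param scheme a `glyco_scheme` (default [default_scheme()]).
#' @param flank window flank used for the embedding (default 10).
#' @return list with `entries` (input plus `matched` logical and
#'   `n_rules_matched`), `matches` (entries x retained rules logical
#'   matrix), `summary_fraction` (fraction of entries matching >=1
#'   retained rule), and `skipped_patterns`.
#' @export
validate_motif_table <- function(entries, rules, scheme = default_scheme(),
                                 flank = 10L) {
  if (is.character(rules)) rules <- rules_from_patterns(rules)
  bad <- substr(entries$sequon, 1L, 1L) != "N"
  if (any(bad)) {
    stop("sequon(s) not starting with N: ",
         paste(entries$sequon[bad], collapse = ", "))
  }
  seq_len_min <- min(nchar(entries$sequon))
  windows <- paste0(strrep(PAD_SYMBOL, flank), entries$sequon,
                    strrep(PAD_SYMBOL, flank + 1L - nchar(entries$sequon)))
  encoded <- encode_window(windows, scheme)

  in_range <- vapply(rules$items, function(it) {
    f <- item_fields(it)
    all(f$position >= 1L & f$position <= seq_len_min - 1L)
  }, logical(1))
  skipped <- rules$pattern[!in_range]
  kept <- rules[in_range, , drop = FALSE]

  if (nrow(kept) == 0L) {
    matches <- matrix(FALSE, nrow = nrow(entries), ncol = 0L)
  } else {
    matches <- vapply(kept$items,
                      function(it) rule_matches(encoded, it),
                      logical(nrow(entries)))
    matches <- matrix(matches, nrow = nrow(entries),
                      dimnames = list(NULL, kept$pattern))
  }
  entries$matched <- rowSums(matches) > 0L
  entries$n_rules_matched <- rowSums(matches)
  list(entries = entries,
       matches = matches,
       summary_fraction = mean(entries$matched),
       skipped_patterns = skipped)
}

#' Read a site-prediction table
#'
#' TSV standing in for an external predictor's output, with columns
#' `protein_id`, `position`, `predicted` (logical or 0/1): every row is
#' an asparagine scored by the predictor.
#'
#' @param path path to the TSV.
#' @return data.frame `protein_id`, `position`, `predicted`.
#' @export
read_prediction_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("protein_id", "position", "predicted")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("prediction table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  data.frame(protein_id = as.character(tab$protein_id),
             position = as.integer(tab$position),
             predicted = as.logical(tab$predicted),
             stringsAsFactors = FALSE)
}

#' Parse a NetNGlyc-style plain-text report (convenience)
#'
#' Extracts (protein, position, predicted) triples from the per-site
#' result lines of the server's text output, which look like
#' `"SEQNAME  123  NRSA  0.5541  (8/9)  +"`. A site is taken as
#' predicted when its result field contains `+`. Lines not matching the
#' layout are ignored.
#'
#' @param path path to the saved plain-text report.
#' @return data.frame `protein_id`, `position`, `predicted`.
#' @export
parse_netnglyc_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pat <- "^\\s*(\\S+)\\s+(\\d+)\\s+(N\\S{2,3})\\s+([0-9.]+)\\s+\\(\\d+/\\d+\\)\\s*(\\+*)\\s*$"
  hit <- grepl(pat, lines)
  if (!any(hit)) {
    return(data.frame(protein_id = character(0), position = integer(0),
                      predicted = logical(0), stringsAsFactors = FALSE))
  }
  m <- regmatches(lines[hit], regexec(pat, lines[hit]))
  data.frame(
    protein_id = vapply(m, `[[`, character(1), 2L),
    position = as.integer(vapply(m, `[[`, character(1), 3L)),
    predicted = nzchar(vapply(m, `[[`, character(1), 6L)),
    stringsAsFactors = FALSE
  )
}

#' Build predicted / non-predicted window sets
#'
#' Splits the asparagines of a prediction table into predicted and
#' non-predicted groups and extracts their context windows, the two
#' peptide datasets used for rule-conformity validation.
#'
#' @param proteins protein data.frame (`id`, `sequence`).
#' @param predictions prediction data.frame (see
#'   [read_prediction_tsv()]).
#' @param flank window flank (default 10).
#' @return list of two window data.frames: `predicted`, `non_predicted`.
#' @export
windows_from_predictions <- function(proteins, predictions, flank = 10L) {
  sites <- data.frame(protein_id = predictions$protein_id,
                      position = predictions$position,
                      residue = "N",
                      label = ifelse(predictions$predicted, "positive",
                                     "negative"),
                      stringsAsFactors = FALSE)
  with_windows <- extract_windows(proteins, sites, flank = flank)
  list(predicted = with_windows[with_windows$label == "positive", ,
                                drop = FALSE],
       non_predicted = with_windows[with_windows$label == "negative", ,
                                    drop = FALSE])
}
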