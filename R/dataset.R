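# Dataset assembly: FASTA + site-table ingestion, cleaning, negative-site
# enumeration, class balancing and context-window extraction.

#' Read protein sequences from a FASTA file
#'
#' Multi-record, wrapped-line FASTA is read with Biostrings. Record ids are
#' the first whitespace-delimited token of each header; sequences are
#' upper-cased.
#'
#' @param path path to a FASTA file of protein sequences.
#' @return data.frame with columns `id`, `sequence`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      stop("malformed FASTA '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicated FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(id = ids, sequence = toupper(as.character(set)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a site-annotation table
#'
#' Tab-separated UTF-8 with a header; required columns `protein_id`,
#' `position`, `label` (an optional `residue` column is carried through).
#' Labels are normalised: `glycosylated`/`N+`/`positive` become
#' `"positive"`, `unannotated`/`N-`/`negative` become `"negative"`.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `protein_id`, `position`, `residue`,
#'   `label`.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  required <- c("protein_id", "position", "label")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("site table '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  lab <- tolower(trimws(tab$label))
  pos_labels <- c("positive", "glycosylated", "n+", "pos", "1", "true")
  neg_labels <- c("negative", "unannotated", "non-glycosylated", "n-",
                  "neg", "0", "false")
  unknown <- !(lab %in% c(pos_labels, neg_labels))
  if (any(unknown)) {
    stop("unrecognised site label(s): ",
         paste(unique(tab$label[unknown]), collapse = ", "))
  }
  data.frame(
    protein_id = as.character(tab$protein_id),
    position = as.integer(tab$position),
    residue = if ("residue" %in% names(tab)) as.character(tab$residue)
              else NA_character_,
    label = ifelse(lab %in% pos_labels, "positive", "negative"),
    stringsAsFactors = FALSE
  )
}

#' Write a site table as TSV
#'
#' @param sites site data.frame (`protein_id`, `position`, `residue`,
#'   `label`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Parse sequence and site inputs together
#'
#' Reads the FASTA and the site table and enforces referential integrity:
#' sites pointing at unknown protein ids are dropped with a warning.
#'
#' @param fasta_path protein FASTA path.
#' @param sites_path site-annotation TSV path.
#' @return list with `proteins`, `sites`, and `n_dropped_unknown`.
#' @export
parse_inputs <- function(fasta_path, sites_path) {
  proteins <- read_protein_fasta(fasta_path)
  sites <- read_site_table(sites_path)
  known <- sites$protein_id %in% proteins$id
  if (any(!known)) {
    warning(sum(!known), " site(s) reference unknown protein id(s) ",
            "and were dropped: ",
            paste(utils::head(unique(sites$protein_id[!known]), 5L),
                  collapse = ", "))
  }
  list(proteins = proteins, sites = sites[known, , drop = FALSE],
       n_dropped_unknown = sum(!known))
}

#' Clean an assembled site dataset
#'
#' Applies the inconsistency and duplication checks in a fixed order, so
#' every input site is counted under exactly one removal class:
#' \enumerate{
#'   \item proteins containing non-standard characters are excluded
#'     entirely (composition statistics would otherwise be polluted) and
#'     their sites counted under `n_nonstandard_char`;
#'   \item duplicate (protein_id, position) entries are collapsed to one;
#'     when the duplicates disagree on the label, the annotated
#'     modification wins (positive) with a warning;
#'   \item positions outside `[1, nchar(sequence)]` are length errors;
#'   \item sites whose residue is not asparagine are position mismatches.
#' }
#' Cleaning is idempotent: applying it to its own output removes nothing.
#'
#' @param proteins data.frame `id`, `sequence`.
#' @param sites site data.frame.
#' @return list with cleaned `proteins`, `sites` and a `cleaning_report`.
#' @export
clean_dataset <- function(proteins, sites) {
  n_input <- nrow(sites)

  bad_seq <- grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"),
                   proteins$sequence)
  bad_ids <- proteins$id[bad_seq]
  nonstd <- sites$protein_id %in% bad_ids
  n_nonstandard <- sum(nonstd)
  proteins <- proteins[!bad_seq, , drop = FALSE]
  sites <- sites[!nonstd, , drop = FALSE]

  # Duplicates on (protein_id, position); positives outrank negatives.
  ord <- order(sites$protein_id, sites$position,
               sites$label != "positive")
  sites <- sites[ord, , drop = FALSE]
  key <- paste(sites$protein_id, sites$position, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    kept_label <- sites$label[match(key[dup], key)]
    if (any(kept_label != sites$label[dup])) {
      warning("conflicting labels at ",
              sum(kept_label != sites$label[dup]),
              " duplicated site(s); resolved to positive")
    }
  }
  n_duplicates <- sum(dup)
  sites <- sites[!dup, , drop = FALSE]

  seq_len_by_id <- stats::setNames(nchar(proteins$sequence), proteins$id)
  plen <- seq_len_by_id[sites$protein_id]
  len_bad <- is.na(sites$position) | sites$position < 1L |
    sites$position > plen
  n_length <- sum(len_bad)
  sites <- sites[!len_bad, , drop = FALSE]

  seq_by_id <- stats::setNames(proteins$sequence, proteins$id)
  at <- substr(seq_by_id[sites$protein_id], sites$position, sites$position)
  mismatch <- at != "N"
  n_mismatch <- sum(mismatch)
  sites <- sites[!mismatch, , drop = FALSE]
  sites$residue <- "N"
  rownames(sites) <- NULL

  report <- structure(
    list(n_input = n_input,
         n_nonstandard_char = n_nonstandard,
         n_duplicates_removed = n_duplicates,
         n_length_error = n_length,
         n_position_mismatch = n_mismatch,
         n_retained = nrow(sites)),
    class = "cleaning_report"
  )
  stopifnot(report$n_retained ==
              report$n_input - n_nonstandard - n_duplicates -
              n_length - n_mismatch)
  list(proteins = proteins, sites = sites, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report\n")
  cat(sprintf("  input sites:            %d\n", x$n_input))
  cat(sprintf("  non-standard sequence:  %d\n", x$n_nonstandard_char))
  cat(sprintf("  duplicates removed:     %d\n", x$n_duplicates_removed))
  cat(sprintf("  length errors:          %d\n", x$n_length_error))
  cat(sprintf("  position mismatches:    %d\n", x$n_position_mismatch))
  cat(sprintf("  retained:               %d\n", x$n_retained))
  invisible(x)
}

#' @export
as.data.frame.cleaning_report <- function(x, ...) {
  data.frame(metric = names(unclass(x)),
             count = unlist(unclass(x), use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Enumerate non-annotated asparagine sites
#'
#' Every asparagine occurrence in the cleaned proteins that is not listed
#' as a positive site becomes a negative site.
#'
#' @param proteins cleaned protein data.frame.
#' @param positive_sites cleaned positive site data.frame.
#' @return site data.frame with `label == "negative"`, disjoint from the
#'   positives.
#' @export
enumerate_negative_sites <- function(proteins, positive_sites) {
  hits <- gregexpr("N", proteins$sequence, fixed = TRUE)
  n_per <- vapply(hits, function(h) sum(h > 0L), integer(1))
  all_n <- data.frame(
    protein_id = rep(proteins$id, n_per),
    position = unlist(lapply(hits, function(h) as.integer(h[h > 0L])),
                      use.names = FALSE),
    stringsAsFactors = FALSE
  )
  pos_key <- paste(positive_sites$protein_id, positive_sites$position,
                   sep = "\r")
  keep <- !(paste(all_n$protein_id, all_n$position, sep = "\r") %in% pos_key)
  out <- all_n[keep, , drop = FALSE]
  out$residue <- rep("N", nrow(out))
  out$label <- rep("negative", nrow(out))
  rownames(out) <- NULL
  out
}

#' Balance negative sites against positives
#'
#' Subsamples the negatives without replacement down to `ratio` times the
#' number of positives, by a shuffle-then-take contract: negatives are
#' ordered deterministically by (protein_id, position), permuted with the
#' seeded generator, and the first k are taken. Identical inputs and seed
#' give an identical subsample.
#'
#' @param positives positive site data.frame.
#' @param negatives negative site data.frame.
#' @param ratio `"1:1"` (default) or `"1:2"` positives-to-negatives.
#' @param seed integer RNG seed (default 42).
#' @return data.frame of the sampled negatives.
#' @export
balance_dataset <- function(positives, negatives, ratio = c("1:1", "1:2"),
                            seed = 42L) {
  ratio <- match.arg(ratio)
  mult <- c("1:1" = 1L, "1:2" = 2L)[[ratio]]
  k <- mult * nrow(positives)
  if (nrow(negatives) < k) {
    stop("insufficient negatives: need ", k, " for ratio ", ratio,
         " but only ", nrow(negatives), " available")
  }
  negatives <- negatives[order(negatives$protein_id, negatives$position),
                         , drop = FALSE]
  idx <- with_seed(seed, sample.int(nrow(negatives)))[seq_len(k)]
  out <- negatives[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the context window around one site
#'
#' Returns the `2*flank+1`-residue peptide centred on the asparagine
#' (offset 0), with positions beyond the protein termini padded with
#' `"-"`. Pads never match any mined item and are excluded from
#' composition counts downstream.
#'
#' @param sequence protein sequence string.
#' @param position 1-based asparagine position.
#' @param flank residues on each side (default 10, giving 21-mers).
#' @return window string of length `2*flank+1`.
#' @export
#' @examples
#' extract_window("MANCSNA", 6, flank = 3)
extract_window <- function(sequence, position, flank = 10L) {
  len <- nchar(sequence)
  if (position < 1L || position > len) {
    stop("position ", position, " outside sequence of length ", len)
  }
  if (substr(sequence, position, position) != "N") {
    stop("residue at position ", position, " is '",
         substr(sequence, position, position), "', not 'N'")
  }
  left <- max(1L, position - flank)
  right <- min(len, position + flank)
  paste0(strrep(PAD_SYMBOL, flank - (position - left)),
         substr(sequence, left, right),
         strrep(PAD_SYMBOL, flank - (right - position)))
}

#' Extract context windows for a site table
#'
#' Vectorised [extract_window()] over a cleaned site table.
#'
#' @param proteins cleaned protein data.frame.
#' @param sites cleaned site data.frame.
#' @param flank residues on each side of the site (default 10).
#' @return `sites` with an added `window` column.
#' @export
extract_windows <- function(proteins, sites, flank = 10L) {
  seq_by_id <- stats::setNames(proteins$sequence, proteins$id)
  missing <- !(sites$protein_id %in% proteins$id)
  if (any(missing)) {
    stop("site(s) reference unknown protein(s): ",
         paste(unique(sites$protein_id[missing]), collapse = ", "))
  }
  sites$window <- mapply(extract_window, seq_by_id[sites$protein_id],
                         sites$position, MoreArgs = list(flank = flank),
                         USE.NAMES = FALSE)
  sites
}
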