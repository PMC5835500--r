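# Test fixtures built in code: tiny FASTA/site files, window samplers,
# and an unplanted mining run used by the null-calibration checks.

write_fixture_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  }))
  writeLines(lines, path)
  path
}

write_fixture_sites <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# Random windows over the residue alphabet with the centre fixed to N,
# optionally forcing `symbol` at `position` with probability q.
random_residue_windows <- function(n, flank = 10, q = 0, symbol = NULL,
                                   position = NULL) {
  m <- matrix(sample(AA_STANDARD, n * (2 * flank + 1), replace = TRUE),
              nrow = n)
  m[, flank + 1] <- "N"
  if (!is.null(symbol) && q > 0) {
    hit <- stats::runif(n) < q
    m[hit, position + flank + 1] <- symbol
  }
  apply(m, 1, paste, collapse = "")
}

# A small carrier protein with printed sequons embedded at given
# positions (1-based position of the N).
carrier_with_sequons <- function(sequons, positions, length_out = 700) {
  chars <- rep("G", length_out)
  for (i in seq_along(sequons)) {
    s <- strsplit(sequons[i], "")[[1]]
    chars[positions[i] + seq_along(s) - 1L] <- s
  }
  paste(chars, collapse = "")
}

# Generate an unplanted synthetic dataset and run the encoded
# assemble -> prefer -> mine chain through the exported API. Returns the
# balanced window sets and the mined rules.
mine_unplanted <- function(seed, n_positives = 1000, n_proteins = 250,
                           protein_length = c(130, 190),
                           grid = seq(5, 95, by = 5), mine = TRUE) {
  cfg <- synthetic_config(
    n_proteins = n_proteins, protein_length = protein_length,
    planted_specs = list(), n_positives = n_positives,
    negatives_per_positive = 1, seed = seed
  )
  ds <- generate_dataset(cfg)
  cleaned <- clean_dataset(ds$proteins, ds$sites)
  negatives <- enumerate_negative_sites(cleaned$proteins, cleaned$sites)
  balanced <- balance_dataset(cleaned$sites, negatives, ratio = "1:1",
                              seed = seed)
  pos <- extract_windows(cleaned$proteins, cleaned$sites)$window
  neg <- extract_windows(cleaned$proteins, balanced)$window
  pos_enc <- encode_window(pos)
  neg_enc <- encode_window(neg)
  if (!mine) return(list(pos = pos_enc, neg = neg_enc))
  pref <- suppressWarnings(preferred_items(pos_enc, class_label = "N+"))
  rules <- sweep_support_grid(eligible_items(pref), pos_enc, neg_enc,
                              grid = grid)
  list(pos = pos_enc, neg = neg_enc, rules = rules, preference = pref)
}
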