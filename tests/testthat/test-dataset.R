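# Dataset assembly: parsing, cleaning, negative enumeration, balancing,
# window extraction.

test_that("parse_inputs reads well-formed input and keeps referential integrity", {
  fasta <- write_fixture_fasta(list(P1 = "MANCS"))
  sites <- write_fixture_sites(data.frame(
    protein_id = "P1", position = 3, residue = "N", label = "positive"))
  parsed <- parse_inputs(fasta, sites)
  expect_equal(nrow(parsed$proteins), 1L)
  expect_equal(nrow(parsed$sites), 1L)
  expect_equal(parsed$sites$label, "positive")

  orphan <- write_fixture_sites(data.frame(
    protein_id = "P9", position = 3, residue = "N", label = "positive"))
  expect_warning(parsed2 <- parse_inputs(fasta, orphan), "unknown protein")
  expect_equal(nrow(parsed2$sites), 0L)
  expect_equal(parsed2$n_dropped_unknown, 1L)
})

test_that("a missing site-table column is a schema error", {
  fasta <- write_fixture_fasta(list(P1 = "MANCS"))
  bad <- write_fixture_sites(data.frame(protein_id = "P1", position = 3))
  expect_error(parse_inputs(fasta, bad), "label")
})

test_that("the four printed cadherin sequons parse and window correctly", {
  sequons <- c("NSTY", "NGSP", "NTSP", "NWTI")
  positions <- c(558, 570, 622, 637)
  fasta <- write_fixture_fasta(list(
    CDH1 = carrier_with_sequons(sequons, positions)))
  sites <- write_fixture_sites(data.frame(
    protein_id = "CDH1", position = positions, residue = "N",
    label = "glycosylated"))
  parsed <- parse_inputs(fasta, sites)
  cleaned <- clean_dataset(parsed$proteins, parsed$sites)
  expect_equal(nrow(cleaned$sites), 4L)
  expect_true(all(cleaned$sites$label == "positive"))

  w <- extract_windows(cleaned$proteins, cleaned$sites, flank = 10)
  # offsets 0..+3 of the N558 window spell the printed sequon
  expect_equal(substr(w$window[w$position == 558], 11, 14), "NSTY")
  expect_equal(substr(w$window[w$position == 637], 11, 14), "NWTI")
})

test_that("cleaning counts each removal class and is idempotent", {
  proteins <- data.frame(
    id = c("P1", "P2"),
    sequence = c("MANCS", "MAXNC"),   # P2 carries a non-standard X
    stringsAsFactors = FALSE
  )
  sites <- data.frame(
    protein_id = c("P1", "P1", "P1", "P1", "P2"),
    position = c(3, 3, 2, 99, 4),
    residue = "N",
    label = c("positive", "positive", "positive", "positive", "positive"),
    stringsAsFactors = FALSE
  )
  cleaned <- clean_dataset(proteins, sites)
  r <- cleaned$report
  expect_equal(r$n_input, 5L)
  expect_equal(r$n_nonstandard_char, 1L)   # P2 site
  expect_equal(r$n_duplicates_removed, 1L) # (P1,3) twice
  expect_equal(r$n_length_error, 1L)       # position 99
  expect_equal(r$n_position_mismatch, 1L)  # (P1,2) is 'A'
  expect_equal(r$n_retained, 1L)
  expect_false("P2" %in% cleaned$proteins$id)

  again <- clean_dataset(cleaned$proteins, cleaned$sites)
  expect_equal(again$report$n_retained, again$report$n_input)
  expect_equal(again$sites, cleaned$sites)
})

test_that("conflicting labels at one site resolve to positive with a warning", {
  proteins <- data.frame(id = "P1", sequence = "MANCS",
                         stringsAsFactors = FALSE)
  sites <- data.frame(protein_id = "P1", position = c(3, 3),
                      residue = "N", label = c("negative", "positive"),
                      stringsAsFactors = FALSE)
  expect_warning(cleaned <- clean_dataset(proteins, sites), "conflicting")
  expect_equal(cleaned$sites$label, "positive")
  expect_equal(cleaned$report$n_duplicates_removed, 1L)
})

test_that("negative enumeration agrees with a direct string scan", {
  proteins <- data.frame(id = "P1", sequence = "MANCSNA",
                         stringsAsFactors = FALSE)
  pos <- data.frame(protein_id = "P1", position = 3, residue = "N",
                    label = "positive", stringsAsFactors = FALSE)
  neg <- enumerate_negative_sites(proteins, pos)
  expect_equal(neg$position, 6L)
  expect_true(all(neg$label == "negative"))

  none <- data.frame(id = "P2", sequence = "MACSA",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(enumerate_negative_sites(none, pos[0, ])), 0L)

  # 100 positives + 1000 planted extra Asn, verified by direct scan
  set.seed(11)
  seqs <- vapply(1:100, function(i) {
    chars <- sample(setdiff(AA_STANDARD, "N"), 40, replace = TRUE)
    chars[20] <- "N"                      # the positive
    extra <- sample(setdiff(1:40, 20), 10)
    chars[extra] <- "N"                   # 10 planted negatives each
    paste(chars, collapse = "")
  }, character(1))
  proteins2 <- data.frame(id = sprintf("Q%03d", 1:100), sequence = seqs,
                          stringsAsFactors = FALSE)
  pos2 <- data.frame(protein_id = proteins2$id, position = 20,
                     residue = "N", label = "positive",
                     stringsAsFactors = FALSE)
  neg2 <- enumerate_negative_sites(proteins2, pos2)
  oracle <- sum(vapply(seqs, function(s) {
    sum(strsplit(s, "")[[1]] == "N") - 1L
  }, integer(1)))
  expect_equal(nrow(neg2), oracle)
  expect_equal(nrow(neg2), 1000L)
  key <- function(df) paste(df$protein_id, df$position)
  expect_length(intersect(key(pos2), key(neg2)), 0L)
})

test_that("balancing subsamples exactly, deterministically, and errors on shortfall", {
  pos <- data.frame(protein_id = "P", position = 1:5, residue = "N",
                    label = "positive", stringsAsFactors = FALSE)
  neg <- data.frame(protein_id = "P", position = 101:112, residue = "N",
                    label = "negative", stringsAsFactors = FALSE)
  b1 <- balance_dataset(pos, neg, ratio = "1:1", seed = 7)
  expect_equal(nrow(b1), 5L)
  b2 <- balance_dataset(pos, neg, ratio = "1:1", seed = 7)
  expect_identical(b1, b2)
  b3 <- balance_dataset(pos, neg, ratio = "1:1", seed = 8)
  expect_false(identical(b1$position, b3$position))
  expect_equal(nrow(balance_dataset(pos, neg, ratio = "1:2", seed = 7)),
               10L)
  expect_error(balance_dataset(pos, neg[1:3, ], ratio = "1:1", seed = 7),
               "insufficient")
})

test_that("windows have the stated length, centre and padding", {
  seq21 <- paste0(strrep("A", 10), "N", strrep("C", 10))
  expect_equal(extract_window(seq21, 11), seq21)

  w <- extract_window("ANCSTGHKLMRSTVWYACDEF", 2)
  expect_equal(nchar(w), 21L)
  expect_equal(substr(w, 1, 9), strrep("-", 9))
  expect_equal(substr(w, 11, 11), "N")

  expect_error(extract_window("MANCS", 2), "not 'N'")
  expect_error(extract_window("MANCS", 9), "outside")

  # pads only as contiguous prefix/suffix; centre always N
  set.seed(3)
  for (i in 1:25) {
    len <- sample(5:40, 1)
    chars <- sample(AA_STANDARD, len, replace = TRUE)
    p <- sample(len, 1)
    chars[p] <- "N"
    w <- extract_window(paste(chars, collapse = ""), p, flank = 10)
    expect_equal(nchar(w), 21L)
    expect_equal(substr(w, 11, 11), "N")
    expect_match(w, "^-*[A-Z]+-*$")
  }
})
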