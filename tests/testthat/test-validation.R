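# Conformity reports, sequon classification and motif-table validation.

test_that("rule matching respects offsets, pads and alphabets", {
  # encoded E-cad N558 context, embedded at offsets 0..3
  win <- paste0(strrep("-", 10), "LLLA", strrep("-", 7))
  expect_true(rule_matches(win, "<L,2>"))
  expect_false(rule_matches(win, "<O,1><L,2>"))  # +1 is L, not O
  expect_false(rule_matches(win, "<L,5>"))       # fully padded offset
  expect_false(rule_matches(win, "<A,-1>"))      # pad matches nothing
  expect_error(rule_matches(win, character(0)), "no items")
})

test_that("conformity counts windows matching any rule, rounded half-up", {
  expect_equal(conformity_percentage(216, 229), 94L)
  expect_equal(conformity_percentage(378, 642), 59L)
  expect_equal(conformity_percentage(195, 229), 85L)
  expect_equal(conformity_percentage(397, 642), 62L)
  expect_equal(conformity_percentage(5, 8), 63L)   # .625 rounds up
  expect_equal(conformity_percentage(1, 200), 1L)  # 0.5 rounds up

  wins <- c("AANOL", "AANGL", "AANGC", "AANCC")
  rep1 <- conformity_report(wins, c("<O,1>", "<L,2>"), "toy")
  expect_equal(rep1$n_matched, 2L)   # first two carry L at +2 / O at +1
  expect_equal(rep1$percentage, 50L)
  expect_equal(rep1$per_rule_counts, c("<O,1>" = 1L, "<L,2>" = 2L))

  rep0 <- conformity_report(wins, rules_from_patterns(character(0)), "none")
  expect_equal(rep0$n_matched, 0L)
  expect_equal(rep0$percentage, 0L)
})

test_that("conformity is monotone in the rule set and consistent with support", {
  set.seed(5)
  wins <- encode_window(random_residue_windows(100, flank = 5))
  r1 <- conformity_report(wins, "<L,2>")
  r2 <- conformity_report(wins, c("<L,2>", "<O,1>"))
  expect_gte(r2$n_matched, r1$n_matched)
  # every window counted in a pattern's support also conforms to it
  expect_equal(r1$n_matched / r1$n_total * 100,
               pattern_support("<L,2>", wins))
})

test_that("alphabet declarations are checked when present", {
  rules <- rules_from_patterns("<L,2>")
  attr(rules, "alphabet") <- "encoded"
  expect_error(conformity_report(c("AANSA"), rules, alphabet = "raw"),
               "alphabet mismatch")
})

test_that("sequon class comes from +2 and the Pro flag from +1", {
  cls <- classify_sequon(c("NSTY", "NNCE", "NYDL", "NGSP", "NPTA"))
  expect_equal(cls$class,
               c("NXT", "NXC", "non-canonical", "NXS", "NXT"))
  expect_equal(cls$x_is_proline, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # full windows: centre located automatically
  win <- extract_window(paste0(strrep("A", 10), "NWTI", strrep("A", 7)), 11)
  expect_equal(classify_sequon(win)$class, "NXT")
  expect_error(classify_sequon("QSTY"), "asparagine")
})

test_that("printed motif tables validate against encoded rules", {
  ecad <- read_motif_table(system.file("extdata", "ecad_motifs.tsv",
                                       package = "glycoctx"))
  expect_equal(nrow(ecad), 4L)
  v <- validate_motif_table(ecad, "<L,2>")
  expect_true(all(v$entries$matched))   # all four have S/T at +2
  expect_equal(v$summary_fraction, 1)

  # NGSP matches the two-item rule (G -> O, S -> L)
  v2 <- validate_motif_table(ecad[ecad$sequon == "NGSP", ],
                             "<O,1><L,2>")
  expect_true(v2$entries$matched)

  # NYDL does not match <L,2> (D encodes to the acidic group)
  nydl <- data.frame(protein = "EGFR", site = "N73", sequon = "NYDL")
  v3 <- validate_motif_table(nydl, "<L,2>")
  expect_false(v3$entries$matched)

  # rules outside the printed 4-mer context are skipped and reported
  v4 <- validate_motif_table(ecad, c("<A,-5><L,2>", "<L,2><P,9>", "<L,2>"))
  expect_setequal(v4$skipped_patterns, c("<A,-5><L,2>", "<L,2><P,9>"))
  expect_true(all(v4$entries$matched))

  expect_error(validate_motif_table(
    data.frame(protein = "p", site = "s", sequon = "QSTY"), "<L,2>"),
    "not starting with N")
})

test_that("prediction tables and server reports parse into site splits", {
  prot <- data.frame(
    id = "P1",
    sequence = paste0(strrep("A", 10), "NST", strrep("A", 8), "NAA",
                      strrep("A", 10)),
    stringsAsFactors = FALSE
  )
  pred_path <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(protein_id = "P1", position = c(11, 22),
               predicted = c(TRUE, FALSE)),
    pred_path, sep = "\t", quote = FALSE, row.names = FALSE)
  preds <- read_prediction_tsv(pred_path)
  sets <- windows_from_predictions(prot, preds)
  expect_equal(nrow(sets$predicted), 1L)
  expect_equal(nrow(sets$non_predicted), 1L)
  expect_equal(substr(sets$predicted$window, 11, 13), "NST")

  report <- c("Name:  P1    Length:  34",
              "----------------------------------------------------------------------",
              "P1   11   NSTA   0.6712   (9/9)   ++",
              "P1   22   NAAA   0.3470   (8/9)   ",
              "----------------------------------------------------------------------")
  rp <- tempfile(fileext = ".txt")
  writeLines(report, rp)
  parsed <- parse_netnglyc_report(rp)
  expect_equal(parsed$position, c(11L, 22L))
  expect_equal(parsed$predicted, c(TRUE, FALSE))
})
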