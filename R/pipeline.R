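# Single-command pipeline: assemble -> clean -> balance -> window ->
# encode -> prefer -> mine (-> validate), writing a reproducible result
# bundle with a manifest.

#' Assemble a pipeline configuration
#'
#' @param fasta protein FASTA path.
#' @param sites site-annotation TSV path.
#' @param out_dir output directory for the result bundle.
#' @param predictions optional prediction TSV (see
#'   [read_prediction_tsv()]) for conformity validation.
#' @param motifs optional motif TSV (see [read_motif_table()]).
#' @param flank window flank (default 10).
#' @param ratio balancing ratio `"1:1"` or `"1:2"`.
#' @param seed balancing seed (default 42).
#' @param alpha preference significance level.
#' @param correction `"none"` or `"BH"`.
#' @param support_grid support thresholds (default `seq(5, 95, by = 5)`).
#' @param maximal_only maximal-only mining (default `TRUE`).
#' @param scheme `glyco_scheme` for the encoded analyses.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta, sites, out_dir,
                            predictions = NULL, motifs = NULL,
                            flank = 10L, ratio = "1:1", seed = 42L,
                            alpha = 0.05, correction = "none",
                            support_grid = seq(5, 95, by = 5),
                            maximal_only = TRUE,
                            scheme = default_scheme()) {
  for (p in c(fasta, sites, predictions, motifs)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  structure(
    list(fasta = fasta, sites = sites, out_dir = out_dir,
         predictions = predictions, motifs = motifs,
         flank = as.integer(flank), ratio = ratio,
         seed = as.integer(seed), alpha = alpha, correction = correction,
         support_grid = support_grid, maximal_only = isTRUE(maximal_only),
         scheme = scheme),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) NULL
    else if (file.exists(p)) p
    else file.path(base, p)
  }
  pipeline_config(
    fasta = resolve(obj$fasta), sites = resolve(obj$sites),
    out_dir = obj$out_dir %||% file.path(base, "glycoctx_out"),
    predictions = resolve(obj$predictions), motifs = resolve(obj$motifs),
    flank = obj$flank %||% 10L, ratio = obj$ratio %||% "1:1",
    seed = obj$seed %||% 42L, alpha = obj$alpha %||% 0.05,
    correction = obj$correction %||% "none",
    support_grid = obj$support_grid %||% seq(5, 95, by = 5),
    maximal_only = obj$maximal_only %||% TRUE
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full context-mining pipeline
#'
#' Executes every stage on the configured inputs and writes a result
#' bundle to `out_dir`: the cleaning report, preference tables and rule
#' sets for all four datasets (raw and encoded alphabet, positive and
#' negative class), optional conformity reports, a summary mirroring the
#' usual assembled-data statistics table, and a manifest with input
#' hashes, the seed and output hashes. A rerun with the same inputs and
#' config is byte-identical.
#'
#' @param config a `pipeline_config` or the path to a YAML file.
#' @param quiet suppress per-stage progress messages.
#' @return Invisibly, a list with all in-memory artifacts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  parsed <- run_stage("parse", parse_inputs(config$fasta, config$sites))
  say("parse: %d proteins, %d sites (%d unknown-protein sites dropped)",
      nrow(parsed$proteins), nrow(parsed$sites), parsed$n_dropped_unknown)

  cleaned <- run_stage("clean", clean_dataset(parsed$proteins, parsed$sites))
  say("clean: retained %d of %d sites", cleaned$report$n_retained,
      cleaned$report$n_input)

  positives <- cleaned$sites[cleaned$sites$label == "positive", ,
                             drop = FALSE]
  explicit_neg <- cleaned$sites[cleaned$sites$label == "negative", ,
                                drop = FALSE]
  enumerated <- run_stage("negatives", {
    enumerate_negative_sites(cleaned$proteins, positives)
  })
  negatives <- unique(rbind(explicit_neg, enumerated))
  say("negatives: %d enumerated (%d explicit)", nrow(negatives),
      nrow(explicit_neg))

  balanced <- run_stage("balance", {
    balance_dataset(positives, negatives, ratio = config$ratio,
                    seed = config$seed)
  })
  say("balance: %s -> %d negatives kept", config$ratio, nrow(balanced))

  pos_w <- run_stage("windows", {
    extract_windows(cleaned$proteins, positives, flank = config$flank)
  })
  neg_w <- run_stage("windows", {
    extract_windows(cleaned$proteins, balanced, flank = config$flank)
  })

  windows <- list(
    raw = list(pos = pos_w$window, neg = neg_w$window),
    encoded = list(pos = encode_window(pos_w$window, config$scheme),
                   neg = encode_window(neg_w$window, config$scheme))
  )

  datasets <- expand.grid(alphabet = c("raw", "encoded"),
                          class = c("pos", "neg"),
                          stringsAsFactors = FALSE)
  preference <- list()
  rules <- list()
  for (i in seq_len(nrow(datasets))) {
    alpha_name <- datasets$alphabet[i]
    cls <- datasets$class[i]
    other <- if (cls == "pos") "neg" else "pos"
    key <- paste(alpha_name, cls, sep = "_")
    preference[[key]] <- run_stage("preference", {
      if (length(windows[[alpha_name]][[cls]]) == 0L) {
        stop("no ", cls, " windows to analyse")
      }
      preferred_items(windows[[alpha_name]][[cls]], alpha = config$alpha,
                      correction = config$correction,
                      class_label = if (cls == "pos") "N+" else "N-")
    })
    rules[[key]] <- run_stage("mining", {
      sweep_support_grid(eligible_items(preference[[key]]),
                         windows[[alpha_name]][[cls]],
                         windows[[alpha_name]][[other]],
                         grid = config$support_grid,
                         maximal_only = config$maximal_only,
                         consequent = if (cls == "pos") "N+" else "N-")
    })
    say("%s: %d preferred items, %d unique rules (%d emitted)", key,
        sum(preference[[key]]$preferred), nrow(rules[[key]]),
        attr(rules[[key]], "n_emitted"))
  }

  conformity <- NULL
  if (!is.null(config$predictions)) {
    conformity <- run_stage("validation", {
      preds <- read_prediction_tsv(config$predictions)
      sets <- windows_from_predictions(cleaned$proteins, preds,
                                       flank = config$flank)
      out <- list(
        predicted_raw = conformity_report(
          sets$predicted$window, rules$raw_pos, "predicted/raw"),
        non_predicted_raw = conformity_report(
          sets$non_predicted$window, rules$raw_neg, "non-predicted/raw"),
        predicted_encoded = conformity_report(
          encode_window(sets$predicted$window, config$scheme),
          rules$encoded_pos, "predicted/encoded"),
        non_predicted_encoded = conformity_report(
          encode_window(sets$non_predicted$window, config$scheme),
          rules$encoded_neg, "non-predicted/encoded")
      )
      out
    })
  }
  motif_validation <- NULL
  if (!is.null(config$motifs)) {
    motif_validation <- run_stage("validation", {
      validate_motif_table(read_motif_table(config$motifs),
                           rules$encoded_pos, scheme = config$scheme,
                           flank = config$flank)
    })
  }

  summary <- list(
    n_proteins = nrow(cleaned$proteins),
    n_positive_sites = nrow(positives),
    n_negative_sites = nrow(negatives),
    n_balanced_negatives = nrow(balanced),
    datasets = lapply(stats::setNames(nm = names(rules)), function(key) {
      r <- rules[[key]]
      thr <- unlist(r$thresholds)
      list(n_preferred_sites = sum(preference[[key]]$preferred),
           n_association_patterns = attr(r, "n_emitted"),
           n_unique_association_patterns = nrow(r),
           support_range = if (length(thr) > 0L) range(thr)
                           else numeric(0))
    })
  )

  run_stage("write", {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- config$out_dir
    utils::write.table(as.data.frame(cleaned$report),
                       file.path(out, "cleaning_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (key in names(preference)) {
      write_preference_tsv(preference[[key]],
                           file.path(out, paste0("preference_", key, ".tsv")))
      write_rules_json(rules[[key]],
                       file.path(out, paste0("rules_", key, ".json")))
      write_rules_tsv(rules[[key]],
                      file.path(out, paste0("rules_", key, ".tsv")))
    }
    if (!is.null(conformity)) {
      conf_df <- do.call(rbind, lapply(conformity, as.data.frame))
      utils::write.table(conf_df, file.path(out, "conformity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(motif_validation)) {
      utils::write.table(motif_validation$entries,
                         file.path(out, "motif_validation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- sort(setdiff(list.files(out), "manifest.json"))
    manifest <- list(
      inputs = as.list(tools::md5sum(
        vapply(c(config$fasta, config$sites, config$predictions,
                 config$motifs),
               identity, character(1)))),
      seed = config$seed,
      flank = config$flank,
      ratio = config$ratio,
      alpha = config$alpha,
      correction = config$correction,
      support_grid = config$support_grid,
      maximal_only = config$maximal_only,
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(file.path(out, outputs))), outputs))
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  say("bundle written to %s", config$out_dir)

  invisible(list(cleaning_report = cleaned$report,
                 preference = preference, rules = rules,
                 conformity = conformity,
                 motif_validation = motif_validation,
                 summary = summary))
}
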