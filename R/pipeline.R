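#' Run the full pipeline on a synthetic session
#'
#' simulate -> bin -> latent fit -> decode (leave-one-out on forced trials,
#' full model elsewhere) -> change-of-mind detection (per-fold models on
#' cross-validated trials) -> analysis battery, with every stage's outputs
#' written to `out_dir` as plain-text artifacts plus a JSON run manifest
#' (config snapshot, seed, file digests). A stage failure halts the run
#' with a stage-named error and leaves a `FAILED` marker naming the stage.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed (all stage substreams derive from it).
#' @param out_dir Output directory (created if needed).
#' @param params A [pipeline_params()] object.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1,
                         out_dir = tempfile("comdecode_run_"),
                         params = pipeline_params()) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  validate_params(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage: ", name, "\n",
                        conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  session <- stage("simulate", {
    s <- simulate_session(config, seed)
    save_session(s, file.path(out_dir, "session.jsonl"))
    write_trials_csv(s, file.path(out_dir, "trials.csv"))
    s
  })

  latents <- stage("fit-latent", {
    binned <- bin_session(session, params)
    model <- fit_gpfa(binned, params = params)
    writeLines(jsonlite::toJSON(list(tau = model$tau,
                                     logLik = model$logLik[model$n_iter],
                                     n_iter = model$n_iter,
                                     converged = model$converged),
                                auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "gpfa.json"))
    infer_latents(model, binned)
  })

  decoding <- stage("decode", {
    loo <- loo_cross_validate(latents, session$trials, params)
    dec <- train_decoder(latents, session$trials, params)
    traces <- decode_trials(dec, latents)
    traces <- dplyr::rows_update(traces, loo$traces,
                                 by = c("trial_id", "time"))
    utils::write.csv(traces, file.path(out_dir, "traces.csv"),
                     row.names = FALSE)
    list(loo = loo, decoder = dec, traces = traces)
  })

  events <- stage("detect-com", {
    forced_traces <- decoding$loo$traces
    cond <- fit_class_conditionals(forced_traces, session$trials, params)
    fold_conds <- lapply(decoding$loo$folds, function(f) {
      tr_ids <- f$train_ids
      fit_class_conditionals(
        decoding$traces[decoding$traces$trial_id %in% tr_ids, ],
        session$trials, params, fold = tr_ids[1])
    })
    ev <- detect_events(decoding$traces, session$trials, cond, params,
                        fold_models = fold_conds)
    utils::write.csv(ev, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    list(calls = ev, conditionals = cond)
  })

  analyses <- stage("analyze", {
    freq <- category_frequency_stats(events$calls)
    utils::write.csv(freq$proportions,
                     file.path(out_dir, "event_frequencies.csv"),
                     row.names = FALSE)
    utils::write.csv(freq$contrasts, file.path(out_dir, "contrasts.csv"),
                     row.names = FALSE)
    rt <- lapply(c("untaken_vs_forced", "zero_free_vs_zero_forced",
                   "blocked_vs_unchanged"), function(g) {
      tryCatch(rt_stats(session$trials, decoding$traces, g, params),
               error = function(e) list(error = conditionMessage(e)))
    })
    names(rt) <- c("untaken_vs_forced", "zero_free_vs_zero_forced",
                   "blocked_vs_unchanged")
    indec <- tryCatch(indecision_regression(decoding$traces,
                                            session$trials, params),
                      error = function(e) list(error = conditionMessage(e)))
    behav <- behavior_choice_stats(session$trials, params)
    summary <- list(
      loo_forced_accuracy = decoding$loo$accuracy,
      n_loo_trials = length(decoding$loo$trial_ids),
      event_rates = stats::setNames(as.list(
        freq$proportions$p), freq$proportions$trial_class),
      rt = lapply(rt, function(r) {
        if (!is.null(r$error)) list(error = r$error)
        else list(median_diff = r$median_diff, p = r$p_value)
      }),
      indecision = if (!is.null(indec$error)) list(error = indec$error)
      else list(slope = indec$slope, ci = indec$conf_int, n = indec$n)
    )
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"),
               file.path(out_dir, "summary.json"))
    list(freq = freq, rt = rt, indecision = indec, behavior = behav)
  })

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("comdecode")),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = config[!vapply(config, is.list, logical(1)) |
                      names(config) == "timing"],
    params = unclass(params),
    digests = as.list(tools::md5sum(files))
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, force = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(list(out_dir = out_dir, session = session, latents = latents,
                 decoding = decoding, events = events, analyses = analyses,
                 manifest = manifest))
}

#' Summarize a pipeline run as a text report
#'
#' Tabulates decoder accuracy, event frequencies with Wilson intervals and
#' chi-square contrasts, reaction-time statistics, the indecision
#' regression, and — when ground truth is present in the fixture — a
#' confusion matrix of ground-truth vs detected events. Missing stage
#' outputs are flagged as gaps.
#'
#' @param out_dir Directory produced by [run_pipeline()].
#' @return The report path, invisibly; the report text is also returned as
#'   the `text` attribute.
#' @export
make_report <- function(out_dir) {
  need <- c("summary.json", "event_frequencies.csv", "contrasts.csv",
            "events.csv", "session.jsonl")
  gaps <- need[!file.exists(file.path(out_dir, need))]
  lines <- c("comdecode pipeline report",
             strrep("=", 40))
  if (length(gaps) > 0) {
    lines <- c(lines, "", "MISSING STAGE OUTPUTS:", paste(" -", gaps))
  }
  if ("summary.json" %in% setdiff(need, gaps)) {
    s <- jsonlite::fromJSON(file.path(out_dir, "summary.json"))
    lines <- c(lines, "",
               sprintf("Forced-choice leave-one-out accuracy: %.3f (n = %d)",
                       s$loo_forced_accuracy, s$n_loo_trials))
    if (!is.null(s$indecision$slope)) {
      lines <- c(lines, sprintf(
        "Indecision regression: slope %.1f ms/unit (95%% CI %.1f..%.1f, n = %d)",
        s$indecision$slope, s$indecision$ci[1], s$indecision$ci[2],
        s$indecision$n))
    }
  }
  if ("event_frequencies.csv" %in% setdiff(need, gaps)) {
    f <- utils::read.csv(file.path(out_dir, "event_frequencies.csv"))
    lines <- c(lines, "", "Change-of-mind frequency by category:",
               sprintf("  %-28s %3d/%3d = %5.1f%% [%.1f, %.1f]",
                       f$trial_class, f$k, f$n, 100 * f$p, 100 * f$lower,
                       100 * f$upper))
    ct <- utils::read.csv(file.path(out_dir, "contrasts.csv"))
    lines <- c(lines, "", "Contrasts (chi-square 2x2):",
               sprintf("  %-22s X2 = %8.2f  p = %.3g", ct$contrast,
                       ct$statistic, ct$p_value))
  }
  if (all(c("events.csv", "session.jsonl") %in% setdiff(need, gaps))) {
    ev <- utils::read.csv(file.path(out_dir, "events.csv"))
    sess <- load_session(file.path(out_dir, "session.jsonl"))
    if (!is.null(sess$ground_truth)) {
      gt <- sess$ground_truth$events
      truth <- gt$event[match(ev$trial_id, gt$trial_id)] %in%
        c("vacillation", "induced_switch")
      cm <- table(truth = truth, detected = ev$is_com)
      lines <- c(lines, "", "Ground truth vs detected (event-eligible trials):",
                 utils::capture.output(print(cm)))
    }
  }
  path <- file.path(out_dir, "report.txt")
  writeLines(lines, path)
  if (length(gaps) > 0) {
    warning("report has gaps: ", paste(gaps, collapse = ", "))
  }
  structure(invisible(path), text = lines)
}
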