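#' Assemble a validated run configuration
#'
#' Defaults mirror the analysis conditions: theta/alpha bands, baseline +
#' six 250-ms windows with five 50-ms subwindows, 20 densities in 0.1-0.6,
#' gamma selected around 1.65 with omega = 1 temporal coupling, and the
#' significance thresholds alpha_behaviour = 0.01, alpha_network = 0.05,
#' alpha_tpdc_surrogate = 0.001. `n_iterations` defaults to 100 here;
#' full-scale analyses raise it (the reference regime is 5000).
#'
#' @param ... Overrides for any configuration key. Unknown keys are rejected.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    simulate = TRUE,
    synth = list(n_subjects = 4, n_rois = 10,
                 n_trials_per_condition = c("CS+" = 6, "CS-" = 4),
                 seed = 1L),
    bands = band_definitions(),
    densities = list(min = 0.1, max = 0.6, n = 20),
    gamma = 1.0,
    omega = 1.0,
    n_iterations = 100L,
    pool_trials = TRUE,
    tpdc = list(order = 3L, q = 4e-5,
                freqs = list(min = 2, max = 45, step = 1),
                n_surrogates = 0L, alpha = 0.05,
                network_nodes = 1:4),
    alpha_behaviour = 0.01,
    alpha_network = 0.05,
    alpha_tpdc_surrogate = 0.001,
    seed = 1L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad) > 0)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  for (nm in names(ov)) {
    if (is.list(cfg[[nm]]) && is.list(ov[[nm]]) && !is.null(names(ov[[nm]]))) {
      sub <- ov[[nm]]
      badsub <- setdiff(names(sub), names(cfg[[nm]]))
      if (nm != "synth" && nm != "bands" && length(badsub) > 0)
        stop("unknown keys in '", nm, "': ", paste(badsub, collapse = ", "))
      cfg[[nm]][names(sub)] <- sub
    } else cfg[[nm]] <- ov[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Write an epoched series block as CSV
#'
#' Long layout: columns `trial`, `roi`, then one column per sample.
#' @param series An `epoched_series`.
#' @param path Output CSV path.
#' @export
write_series <- function(series, path) {
  d <- series$data
  n_trials <- dim(d)[1]; N <- dim(d)[2]; n_samp <- dim(d)[3]
  M <- matrix(aperm(d, c(2, 1, 3)), n_trials * N, n_samp)
  df <- data.frame(trial = rep(seq_len(n_trials), each = N),
                   roi = rep(series$roi_names, times = n_trials))
  df <- cbind(df, as.data.frame(M))
  names(df)[-(1:2)] <- paste0("s", seq_len(n_samp))
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read an epoched series block written by [write_series()]
#'
#' @param path CSV path.
#' @param metadata List with at least `fs`, `t0_index`, `roi_names`; usually
#'   read from the cohort's `metadata.json`.
#' @param subject,condition Labels to attach.
#' @return An `epoched_series`.
#' @export
read_series <- function(path, metadata, subject = NA_character_,
                        condition = NA_character_) {
  for (key in c("fs", "t0_index", "roi_names"))
    if (is.null(metadata[[key]]))
      stop("metadata is missing required key '", key, "'")
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("trial", "roi") %in% names(df)))
    stop("malformed series CSV ", path, ": need 'trial' and 'roi' columns")
  roi_names <- as.character(metadata$roi_names)
  unknown <- setdiff(unique(df$roi), roi_names)
  if (length(unknown) > 0)
    warning("series contains ROI labels not in the reference list: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  trials <- sort(unique(df$trial))
  n_samp <- ncol(df) - 2L
  N <- length(roi_names)
  data <- array(0, dim = c(length(trials), N, n_samp))
  for (ti in seq_along(trials)) {
    blk <- df[df$trial == trials[ti], , drop = FALSE]
    blk <- blk[match(roi_names, blk$roi), , drop = FALSE]
    data[ti, , ] <- as.matrix(blk[, -(1:2)])
  }
  structure(list(subject = subject, condition = condition, data = data,
                 fs = metadata$fs, t0_index = metadata$t0_index,
                 roi_names = roi_names),
            class = "epoched_series")
}

config_hash <- function(cfg) {
  # small stable hash of the serialized configuration
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 12, force = TRUE)
  sum(utf8ToInt(as.character(s)) * (seq_len(nchar(s)) %% 257)) %% 1e9
}

stage_done <- function(dir, stage, hash) {
  f <- file.path(dir, paste0(".", stage, ".done.json"))
  if (!file.exists(f)) return(FALSE)
  rec <- jsonlite::read_json(f)
  identical(as.numeric(rec$hash), as.numeric(hash))
}

mark_stage <- function(dir, stage, hash) {
  jsonlite::write_json(list(stage = stage, hash = hash,
                            finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                       file.path(dir, paste0(".", stage, ".done.json")),
                       auto_unbox = TRUE)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate, preprocess, connectivity, communities, metrics, tpdc
#' and stats in order, writing per-stage outputs and a manifest under
#' `out_dir`. Completed stages (matching configuration hash) are skipped on
#' re-runs unless `force = TRUE`.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory.
#' @param force Recompute stages even if marked complete.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(config))
  manifest <- list(config = unclass(config), hash = hash, stages = list())
  t_all <- Sys.time()
  stage <- function(name, fun) {
    t0 <- Sys.time()
    skipped <- FALSE
    if (!force && stage_done(out_dir, name, hash)) {
      skipped <- TRUE
    } else {
      fun()
      mark_stage(out_dir, name, hash)
    }
    manifest$stages[[length(manifest$stages) + 1]] <<- list(
      name = name, skipped = skipped,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  data_dir <- file.path(out_dir, "cohort")
  synth_cfg <- do.call(synthetic_config, config$synth)
  conditions <- names(synth_cfg$n_trials_per_condition)
  n_sub <- synth_cfg$n_subjects
  subjects <- sprintf("S%02d", seq_len(n_sub))
  cond_file <- function(cond) gsub("[+]", "plus", gsub("[-]", "minus", cond))
  scheme <- window_scheme()
  densities <- with(config$densities, density_grid(min, max, n))

  stage("simulate", function() {
    generate_cohort(synth_cfg, data_dir, overwrite = TRUE, write_series = TRUE)
  })
  meta <- jsonlite::read_json(file.path(data_dir, "metadata.json"),
                              simplifyVector = TRUE)

  load_series <- function(s, cond) {
    ser <- read_series(file.path(data_dir, sprintf("series_%s_%s.csv",
                                                   s, cond_file(cond))),
                       meta, subject = s, condition = cond)
    bandpass_filter(ser)
  }

  conn_dir <- file.path(out_dir, "connectivity")
  stage("preprocess", function() {
    # broadband filter happens on load; this stage validates epochs/windows
    ser <- load_series(subjects[1], conditions[1])
    invisible(slice_windows(ser, scheme))
  })

  stage("connectivity", function() {
    dir.create(conn_dir, showWarnings = FALSE)
    for (s in subjects) for (cond in conditions) {
      ser <- load_series(s, cond)
      for (bn in names(config$bands)) {
        env <- band_envelope(ser, config$bands[[bn]])
        env_series <- ser; env_series$data <- env
        blocks <- slice_windows(env_series, scheme)
        for (w in names(blocks)) {
          W <- envelope_correlation_matrix(blocks[[w]], config$pool_trials)
          utils::write.csv(W, file.path(conn_dir, sprintf(
            "W_%s_%s_%s_%s.csv", s, cond_file(cond), bn, w)), row.names = FALSE)
        }
        # subwindow matrices (flexibility layers) for post-stimulus windows
        for (wi in which(scheme$name != "baseline")) {
          off <- subwindow_offsets(scheme$start_ms[wi], scheme$end_ms[wi],
                                   ser$fs)
          for (k in seq_len(nrow(off))) {
            idx <- (ser$t0_index + off$start_offset[k]):(ser$t0_index + off$end_offset[k] - 1L)
            Wk <- envelope_correlation_matrix(env[, , idx, drop = FALSE], TRUE)
            utils::write.csv(Wk, file.path(conn_dir, sprintf(
              "Wsub_%s_%s_%s_%s_%d.csv", s, cond_file(cond), bn,
              scheme$name[wi], k)), row.names = FALSE)
          }
        }
      }
    }
  })

  comm_dir <- file.path(out_dir, "communities")
  stage("communities", function() {
    dir.create(comm_dir, showWarnings = FALSE)
    for (s in subjects) for (cond in conditions) for (bn in names(config$bands)) {
      base_W <- as.matrix(utils::read.csv(file.path(conn_dir, sprintf(
        "W_%s_%s_%s_baseline.csv", s, cond_file(cond), bn))))
      cp <- consensus_partition(base_W, config$gamma, config$n_iterations,
                                seed = config$seed)
      utils::write.csv(data.frame(roi = synth_cfg$roi_names,
                                  community = cp$labels,
                                  stability = cp$stability),
                       file.path(comm_dir, sprintf("baseline_%s_%s_%s.csv",
                                                   s, cond_file(cond), bn)),
                       row.names = FALSE)
      for (wi in which(scheme$name != "baseline")) {
        mats <- lapply(1:5, function(k) as.matrix(utils::read.csv(
          file.path(conn_dir, sprintf("Wsub_%s_%s_%s_%s_%d.csv",
                                      s, cond_file(cond), bn,
                                      scheme$name[wi], k)))))
        names(mats) <- paste0("sub", 1:5)
        da <- dynamic_assignment(mats, config$gamma, config$omega,
                                 max(10L, config$n_iterations %/% 5L),
                                 seed = config$seed + wi)
        utils::write.csv(as.data.frame(da$Q), file.path(comm_dir, sprintf(
          "Q_%s_%s_%s_%s.csv", s, cond_file(cond), bn, scheme$name[wi])),
          row.names = FALSE)
      }
    }
  })

  metric_file <- file.path(out_dir, "metrics.csv")
  stage("metrics", function() {
    rows <- list()
    for (s in subjects) for (cond in conditions) for (bn in names(config$bands)) {
      for (w in scheme$name) {
        W <- as.matrix(utils::read.csv(file.path(conn_dir, sprintf(
          "W_%s_%s_%s_%s.csv", s, cond_file(cond), bn, w))))
        Q <- NULL
        if (w != "baseline") {
          Q <- as.matrix(utils::read.csv(file.path(comm_dir, sprintf(
            "Q_%s_%s_%s_%s.csv", s, cond_file(cond), bn, w))))
        }
        mt <- metrics_over_densities(W, densities, Q = Q)
        mt$subject <- s; mt$condition <- cond; mt$band <- bn; mt$window <- w
        rows[[length(rows) + 1]] <- mt
      }
    }
    utils::write.csv(do.call(rbind, rows), metric_file, row.names = FALSE)
  })

  tpdc_file <- file.path(out_dir, "tpdc_summary.csv")
  stage("tpdc", function() {
    tp_cfg <- config$tpdc
    freqs <- with(tp_cfg$freqs, seq(min, max, by = step))
    nodes <- tp_cfg$network_nodes
    rows <- list()
    for (s in subjects) for (cond in conditions) {
      ser <- load_series(s, cond)
      n_tr <- dim(ser$data)[1]
      acc <- NULL
      for (tr in seq_len(n_tr)) {
        X <- t(ser$data[tr, nodes, ])
        model <- fit_dekf_mvar(X, order = tp_cfg$order, q = tp_cfg$q,
                               fs = ser$fs)
        tp <- tpdc_spectrum(model, freqs = freqs)
        for (bn in names(config$bands)) for (w in scheme$name) {
          wi <- match(w, scheme$name)
          s0 <- ser$t0_index + ms_to_offset(scheme$start_ms[wi], ser$fs)
          s1 <- ser$t0_index + ms_to_offset(scheme$end_ms[wi], ser$fs) - 1L
          sm <- tryCatch(band_window_summary(tp, config$bands[[bn]], s0:s1),
                         error = function(e) NULL)
          if (is.null(sm)) next
          sm$subject <- s; sm$condition <- cond; sm$band <- bn; sm$window <- w
          sm$trial <- tr
          rows[[length(rows) + 1]] <- sm
        }
      }
    }
    tab <- do.call(rbind, rows)
    agg <- stats::aggregate(value ~ source + target + subject + condition +
                              band + window, data = tab, FUN = mean)
    utils::write.csv(agg, tpdc_file, row.names = FALSE)
  })

  stats_dir <- file.path(out_dir, "stats")
  stage("stats", function() {
    dir.create(stats_dir, showWarnings = FALSE)
    behaviour <- utils::read.csv(file.path(data_dir, "behaviour.csv"))
    bt <- list()
    for (var in c("rating", "heart_rate")) {
      a <- behaviour[[var]][behaviour$condition == "CS+"]
      b <- behaviour[[var]][behaviour$condition == "CS-"]
      ord_a <- order(behaviour$subject[behaviour$condition == "CS+"])
      ord_b <- order(behaviour$subject[behaviour$condition == "CS-"])
      bt[[var]] <- paired_ttest(a[ord_a], b[ord_b],
                                alpha = config$alpha_behaviour)
    }
    jsonlite::write_json(bt, file.path(stats_dir, "behaviour_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    metrics <- utils::read.csv(metric_file)
    out <- list()
    for (bn in names(config$bands)) for (m in unique(metrics$metric)) {
      sub <- metrics[metrics$band == bn & metrics$metric == m, ]
      # average across densities per cell before testing
      cell <- stats::aggregate(value ~ subject + condition + window,
                               data = sub, FUN = mean)
      names(cell)[names(cell) == "window"] <- "time"
      an <- tryCatch(rm_anova_2way(cell), error = function(e) NULL)
      if (!is.null(an)) {
        tabr <- an$table
        tabr$band <- bn; tabr$metric <- m
        out[[length(out) + 1]] <- tabr
      }
    }
    utils::write.csv(do.call(rbind, out), file.path(stats_dir, "anova.csv"),
                     row.names = FALSE)
  })

  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
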