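# End-to-end pipeline: simulate -> fd -> pairs -> acf -> anova -> predict,
# with a plain-text config, stage-tagged logging and a hashed run manifest.

#' Parse a plain-text run configuration
#'
#' INI-style format: `[section]` headers with `key = value` lines; `#`
#' starts a comment. Values are parsed as numbers when possible; comma
#' separation gives vectors; `name:value` pairs give named vectors.
#'
#' @param path Config file path.
#' @return Nested named list (one element per section), with the raw lines
#'   attached as attribute `"source"` for provenance echoing.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_scanseq(sprintf("config not found: %s", path), "scanseq_io_error")
  }
  lines <- readLines(path)
  cfg <- list()
  section <- "global"
  for (ln in lines) {
    s <- sub("#.*$", "", ln)
    s <- trimws(s)
    if (!nzchar(s)) next
    if (grepl("^\\[.+\\]$", s)) {
      section <- gsub("^\\[|\\]$", "", s)
      next
    }
    kv <- strsplit(s, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) {
      stop_scanseq(sprintf("malformed config line: '%s'", ln),
                   "scanseq_parse_error")
    }
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    if (all(grepl(":", parts, fixed = TRUE))) {
      nm <- vapply(strsplit(parts, ":", fixed = TRUE), `[`, "", 1)
      vv <- vapply(strsplit(parts, ":", fixed = TRUE), `[`, "", 2)
      num <- suppressWarnings(as.numeric(vv))
      parsed <- stats::setNames(if (anyNA(num)) vv else num, trimws(nm))
    } else {
      num <- suppressWarnings(as.numeric(parts))
      parsed <- if (anyNA(num)) parts else num
    }
    cfg[[section]][[key]] <- parsed
  }
  structure(cfg, source = lines)
}

#' Default run configuration
#'
#' The stated study design: 100 cases (50% malignant, 25% benign, 25%
#' normal), 10 readers in tiers 3/4/3, 60-Hz gaze sampling on dual displays,
#' lag depths 0..5.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return Nested config list matching [read_run_config()].
#' @export
default_run_config <- function(seed = 1L, out_dir = "scanseq_run") {
  list(
    global = list(seed = seed, out_dir = out_dir),
    study = list(readers = c(N = 3, A = 4, E = 3), cases = 100,
                 bias_alpha = 0, duration = 20, rate = 60,
                 accuracy = c(N = 0.55, A = 0.65, E = 0.75)),
    fractal = list(grid_size = 512),
    analysis = list(max_lag = 20, lags = 0:5, alpha = 0.05,
                    terms = c("F0", "P0", "D1"), coding = 7),
    prediction = list(model = "random_forest", ntree = 500, reps = 1000)
  )
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

config_meta <- function(cfg) {
  flat <- list()
  for (sec in names(cfg)) {
    for (k in names(cfg[[sec]])) {
      v <- cfg[[sec]][[k]]
      flat[[paste0("cfg.", sec, ".", k)]] <-
        paste(if (!is.null(names(v)) && any(nzchar(names(v))))
          paste0(names(v), ":", v) else as.character(v), collapse = ",")
    }
  }
  flat
}

#' Run the full analysis pipeline
#'
#' Simulates a study, computes per-reading FD, builds lag-pair datasets,
#' computes per-reader ACFs, runs the fixed-effects ANOVA and the
#' leave-one-case-out prediction sweep, writing every stage as a TSV with
#' the full configuration echoed into its header, plus a manifest of output
#' files with content hashes. Deterministic end to end given the seed.
#'
#' @param config Nested config list ([default_run_config()]) or a path to a
#'   config file ([read_run_config()]).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest data.frame.
#' @export
run_pipeline <- function(config = default_run_config()) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  base <- default_run_config()
  for (sec in names(base)) {
    for (k in names(base[[sec]])) {
      if (is.null(cfg[[sec]][[k]])) cfg[[sec]][[k]] <- base[[sec]][[k]]
    }
  }
  seed <- as.integer(cfg$global$seed)
  out_dir <- as.character(cfg$global$out_dir)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop_scanseq(sprintf("cannot create output directory %s", out_dir),
                   "scanseq_filesystem_error")
    }
  }
  meta <- config_meta(cfg)
  paths <- character(0)
  emit <- function(name, df, num_cols = character(0)) {
    p <- file.path(out_dir, name)
    write_tsv_with_meta(p, df, meta, num_cols)
    paths[[length(paths) + 1L]] <<- p
    p
  }

  sc <- cfg$study
  log_stage("simulate", "%d cases, readers %s, bias_alpha=%g, seed=%d",
            sc$cases, paste(sc$readers, collapse = "/"), sc$bias_alpha, seed)
  study <- generate_study(
    n_readers_per_tier = sc$readers, n_cases = as.integer(sc$cases),
    accuracy = sc$accuracy, bias_alpha = sc$bias_alpha,
    duration = sc$duration, rate = sc$rate, seed = seed)
  emit("cases.tsv", transform(study$cases,
                              pathology = as.character(pathology)))
  emit("readings.tsv", study$readings, num_cols = "duration")
  emit("gaze.tsv", study$gaze, num_cols = c("t", "x", "y"))

  gsz <- as.integer(cfg$fractal$grid_size)
  log_stage("fd", "box-counting FD on grid %d", gsz)
  fd_tab <- study_fd_table(study, grid_size = gsz)
  emit("fd.tsv", fd_tab, num_cols = c("fd", "r2"))

  ann <- annotate_readings(study, fd_table = fd_tab,
                           coding = as.character(cfg$analysis$coding))

  lags <- as.integer(cfg$analysis$lags)
  log_stage("pairs", "lag depths %s", paste(lags, collapse = ","))
  per <- split_readers(ann)
  for (i in lags) {
    tab <- do.call(rbind, lapply(names(per), function(rid) {
      ds <- build_lag_pairs(per[[rid]], i)
      if (nrow(ds)) cbind(reader_id = rid, as.data.frame(ds)) else NULL
    }))
    emit(sprintf("pairs_lag%d.tsv", i), tab,
         num_cols = grep("^F", names(tab), value = TRUE))
  }

  log_stage("acf", "max_lag %d", as.integer(cfg$analysis$max_lag))
  acf_tab <- study_acf_table(ann, max_lag = as.integer(cfg$analysis$max_lag))
  emit("acf.tsv", acf_tab, num_cols = c("r", "band"))

  terms <- as.character(cfg$analysis$terms)
  log_stage("anova", "terms: %s", paste(terms, collapse = " "))
  max_term_lag <- max(vapply(terms, function(tt)
    max(as.integer(substr(parse_term(tt), 2, 2))), integer(1)))
  anova_tab <- do.call(rbind, lapply(names(per), function(rid) {
    ds <- build_lag_pairs(per[[rid]], max(max_term_lag, 1L))
    et <- suppressWarnings(
      fixed_effects_anova(ds, terms, alpha = cfg$analysis$alpha))
    cbind(reader_id = rid, as.data.frame(et))
  }))
  anova_tab <- anova_tab[order(anova_tab$p), ]
  emit("anova.tsv", anova_tab, num_cols = c("F", "p"))

  pc <- cfg$prediction
  log_stage("predict", "%s, ntree=%d, %d baseline reps",
            pc$model, as.integer(pc$ntree), as.integer(pc$reps))
  spec <- model_spec(family = as.character(pc$model),
                     ntree = as.integer(pc$ntree),
                     seed = substream_seed(seed, "predict"))
  report <- sweep_lags(study, lags = lags, spec = spec, fd_table = fd_tab,
                       baseline_reps = as.integer(pc$reps))
  emit("predict.tsv", report, num_cols = c("f_weighted", "baseline"))
  emit("predict_table.tsv", format_report_table(report))

  manifest <- data.frame(
    stage = sub("\\.tsv$", "", sub("_lag[0-9]+$", "", basename(paths))),
    file = basename(paths),
    md5 = unname(tools::md5sum(unlist(paths))),
    stringsAsFactors = FALSE)
  write_tsv_with_meta(file.path(out_dir, "manifest.tsv"), manifest, meta)
  log_stage("done", "%d files in %s", length(paths) + 1L, out_dir)

  invisible(list(study = study, fd = fd_tab, acf = acf_tab,
                 anova = anova_tab, report = report, manifest = manifest,
                 config = cfg, out_dir = out_dir))
}
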