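# Pipeline surface: configuration, logging, and the staged
# synth -> preprocess -> extract -> analyze driver. All artifacts are
# plain CSV/JSON so a run is inspectable and resumable per stage.

.default_config <- function() {
  list(
    out_dir = NULL,
    seed = 1,
    overwrite = FALSE,
    synth = NULL,                    # list of synth_spec() arguments
    segment_snr_db = 5,              # segment quality threshold
    beat_snr_db = 5,                 # per-beat exclusion threshold
    min_participants = 8,
    alpha = 0.01,
    n_tests = 24,
    min_beats = 20,                  # detector rejection rule
    extract_max_steps = 2000,
    extract_patience = 200,
    extractor = "baseline"           # "baseline" or path handled upstream
  )
}

#' Pipeline run configuration
#'
#' All thresholds default to the published analysis settings: 5 dB
#' segment quality filter, 5 dB per-beat exclusion, at least 8
#' participants per age level, significance at corrected p < 0.01 with
#' a 24-test Bonferroni correction, 20-beat detector rejection, and
#' 2000-step / 200-patience extraction episodes.
#'
#' @param out_dir Artifact directory (required).
#' @param ... Overrides of the defaults; an unknown key is an error
#'   naming the key.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, ...) {
  cfg <- .default_config()
  cfg$out_dir <- out_dir
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (is.null(cfg$out_dir)) stop("out_dir is required")
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file path.
#' @param config A [run_config()].
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, lst)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  cat(msg, "\n", file = log_path, append = TRUE, sep = "")
}

#' Run the full pipeline
#'
#' Executes the stages `synth` (when the config carries a synthetic
#' spec) -> `preprocess` -> `extract` -> `analyze`, writing every
#' stage's outputs under `config$out_dir`:
#' `traces/*.csv` and `truth.csv` (synth), `quality.csv` and
#' `epochs/*.csv` (preprocess), `fits.csv` (extract),
#' `aggregated.csv` and `correlations.csv` (analyze), plus `log.txt`
#' recording the package version, seed and config hash. A stage whose
#' primary output already exists is skipped unless
#' `config$overwrite`; a stage whose upstream artifact is missing
#' stops with a stage-dependency error.
#'
#' @param config A [run_config()].
#' @return The artifact directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "log.txt")
  cfg_path <- file.path(out, "config.json")
  write_run_config(config, cfg_path)
  .log_line(log_path, "ecglognorm ",
            as.character(utils::packageVersion("ecglognorm")),
            " seed=", config$seed,
            " config_md5=", unname(tools::md5sum(cfg_path)))
  fresh <- function(path) config$overwrite || !file.exists(path)

  # --- synth ------------------------------------------------------
  truth_path <- file.path(out, "truth.csv")
  traces_dir <- file.path(out, "traces")
  if (!is.null(config$synth)) {
    if (fresh(truth_path)) {
      .log_line(log_path, "stage synth: generating dataset")
      spec <- do.call(synth_spec, config$synth)
      ds <- generate_dataset(spec, seed = config$seed, render = TRUE)
      dir.create(traces_dir, showWarnings = FALSE)
      utils::write.csv(ds$truth, truth_path, row.names = FALSE)
      for (rid in names(ds$segments)) {
        tr <- ds$segments[[rid]]
        write_ecg_csv(tr$segment,
                      file.path(traces_dir,
                                paste0(tr$segment$segment_id, ".csv")))
      }
    } else .log_line(log_path, "stage synth: outputs exist, skipped")
  }

  # --- preprocess -------------------------------------------------
  quality_path <- file.path(out, "quality.csv")
  epochs_dir <- file.path(out, "epochs")
  if (fresh(quality_path)) {
    if (!dir.exists(traces_dir))
      stop("stage-dependency error: no traces/ directory under ", out)
    files <- list.files(traces_dir, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0)
      stop("stage-dependency error: traces/ is empty")
    dir.create(epochs_dir, showWarnings = FALSE)
    .log_line(log_path, "stage preprocess: ", length(files), " trace(s)")
    qrows <- list()
    for (f in files) {
      sid <- sub("\\.csv$", "", basename(f))
      seg <- resample_to_1024(read_ecg_csv(f, segment_id = sid))
      peaks <- tryCatch(detect_r_peaks(seg, min_beats = config$min_beats),
                        segment_rejected = function(e) NULL)
      if (is.null(peaks)) {
        qrows[[sid]] <- data.frame(segment_id = sid, n_beats = 0,
                                   snr_bar_db = NA_real_, kept = FALSE)
        .log_line(log_path, "  ", sid, ": rejected by detector")
        next
      }
      eps <- epoch_beats(seg, peaks)
      q <- segment_quality(eps, segment_id = sid)
      kept <- q$snr_bar >= config$segment_snr_db
      qrows[[sid]] <- data.frame(segment_id = sid, n_beats = q$n_beats,
                                 snr_bar_db = q$snr_bar, kept = kept)
      if (kept) {
        xm <- t(vapply(eps, `[[`, numeric(500), "x"))
        colnames(xm) <- sprintf("s%03d", 1:500)
        utils::write.csv(
          cbind(data.frame(
            beat_id = vapply(eps, `[[`, "", "beat_id"),
            alpha_s = vapply(eps, `[[`, 0, "alpha")), xm),
          file.path(epochs_dir, paste0(sid, ".csv")), row.names = FALSE)
      }
    }
    utils::write.csv(do.call(rbind, qrows), quality_path,
                     row.names = FALSE)
  } else .log_line(log_path, "stage preprocess: outputs exist, skipped")

  # --- extract ----------------------------------------------------
  fits_path <- file.path(out, "fits.csv")
  if (fresh(fits_path)) {
    efiles <- list.files(epochs_dir, pattern = "\\.csv$",
                         full.names = TRUE)
    if (length(efiles) == 0)
      stop("stage-dependency error: no kept epochs under ", epochs_dir)
    cfg <- extraction_config(max_steps = config$extract_max_steps,
                             patience = config$extract_patience)
    all_fits <- list()
    for (f in efiles) {
      sid <- sub("\\.csv$", "", basename(f))
      tab <- utils::read.csv(f)
      eps <- lapply(seq_len(nrow(tab)), function(i) {
        be <- beat_epoch(as.numeric(tab[i, sprintf("s%03d", 1:500)]),
                         0, tab$alpha_s[i], 2 * tab$alpha_s[i],
                         beat_id = tab$beat_id[i])
        be
      })
      bx <- batch_extract("baseline", eps, cfg,
                          exclude_below_db = config$beat_snr_db,
                          seed = config$seed)
      bx$fits$segment_id <- sid
      all_fits[[sid]] <- bx$fits
      .log_line(log_path, "stage extract: ", sid, " ",
                nrow(bx$fits), " beats, ", bx$n_excluded, " excluded")
    }
    utils::write.csv(do.call(rbind, all_fits), fits_path,
                     row.names = FALSE)
  } else .log_line(log_path, "stage extract: outputs exist, skipped")

  # --- analyze ----------------------------------------------------
  corr_path <- file.path(out, "correlations.csv")
  if (fresh(corr_path)) {
    if (!file.exists(fits_path))
      stop("stage-dependency error: fits.csv missing under ", out)
    fits <- utils::read.csv(fits_path)
    if (!file.exists(truth_path))
      stop("stage-dependency error: truth.csv (segment metadata) missing")
    meta <- utils::read.csv(truth_path)
    # detected beats need not align one-to-one with generated beats;
    # recording/subject/age metadata is segment-level, so join on that
    seg_meta <- unique(meta[, c("segment_id", "recording_id", "subject",
                                "age_months")])
    agg <- aggregate_fits(merge(fits, seg_meta, by = "segment_id"))
    kept <- filter_age_levels(agg, min_n = config$min_participants)
    # D parameters reported in uV*s x 1e6 for readability
    agg_out <- agg
    dcols <- grep("_D$", names(agg_out), value = TRUE)
    agg_out[dcols] <- agg_out[dcols] * 1e6
    utils::write.csv(agg_out, file.path(out, "aggregated.csv"),
                     row.names = FALSE)
    corr <- age_correlations(kept, alpha = config$alpha,
                             n_tests = config$n_tests)
    utils::write.csv(corr, corr_path, row.names = FALSE)
    .log_line(log_path, "stage analyze: ",
              sum(corr$significant, na.rm = TRUE),
              " significant parameter(s)")
  } else .log_line(log_path, "stage analyze: outputs exist, skipped")

  invisible(out)
}
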