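#' Load and preprocess a cohort CSV
#'
#' Reads a subjects-by-features table and applies the preprocessing the
#' network reconstruction needs: only numeric information is kept. Textual
#' yes/no columns are mapped to 1/0, logical columns to 1/0, and any other
#' non-numeric column is dropped (with a warning naming it); the label
#' column is coerced to \{0, 1\}. A `subject_id` column is used if present
#' and synthesized otherwise.
#'
#' @param path CSV file with a header row (comma separator, `.` decimal).
#' @param label_col Name of the binary survival label column (1 = died).
#' @return A cohort tibble (`subject_id`, label, numeric features) with
#'   attributes `dropped_columns` and `converted_columns` recording the
#'   preprocessing manifest.
#' @export
load_cohort <- function(path, label_col = "DEATH") {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!label_col %in% names(raw)) {
    abort(paste0("label column '", label_col, "' not found in ", path))
  }
  lab <- map_binary(raw[[label_col]])
  if (is.null(lab)) {
    abort(paste0("label column '", label_col, "' is not interpretable as 0/1"))
  }
  ids <- if ("subject_id" %in% names(raw)) {
    as.character(raw$subject_id)
  } else sprintf("S%05d", seq_len(nrow(raw)))

  feat_cols <- setdiff(names(raw), c("subject_id", label_col))
  dropped <- character(0)
  converted <- character(0)
  feats <- list()
  for (nm in feat_cols) {
    col <- raw[[nm]]
    if (is.numeric(col)) {
      feats[[nm]] <- as.numeric(col)
    } else if (is.logical(col)) {
      feats[[nm]] <- as.numeric(col)
      converted <- c(converted, nm)
    } else {
      mapped <- map_binary(col)
      if (!is.null(mapped)) {
        feats[[nm]] <- as.numeric(mapped)
        converted <- c(converted, nm)
      } else {
        dropped <- c(dropped, nm)
      }
    }
  }
  if (length(dropped) > 0) {
    warn(paste0("dropped non-numeric column(s): ", paste(dropped, collapse = ", ")))
  }
  cohort <- dplyr::bind_cols(
    tibble::tibble(subject_id = ids, "{label_col}" := as.integer(lab)),
    tibble::as_tibble(feats))
  attr(cohort, "dropped_columns") <- dropped
  attr(cohort, "converted_columns") <- converted
  cohort
}

# yes/no, true/false, 0/1 (numeric or text) -> integer 0/1, else NULL.
map_binary <- function(x) {
  if (is.numeric(x)) {
    if (all(x %in% c(0, 1) | is.na(x))) return(as.integer(x)) else return(NULL)
  }
  if (is.logical(x)) return(as.integer(x))
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(v))
  out[v %in% c("yes", "y", "true", "1")] <- 1L
  out[v %in% c("no", "n", "false", "0")] <- 0L
  if (any(is.na(out) & !is.na(v) & v != "")) return(NULL)
  out
}

#' Write a cohort table as CSV
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Draw a balanced subsample of a cohort
#'
#' Samples `n_total` subjects without replacement, exactly half from each
#' class, mirroring the balanced-subset construction used before
#' classification so that accuracy is a meaningful score.
#'
#' @param cohort Cohort tibble.
#' @param n_total Even total number of subjects wanted.
#' @param seed Integer seed.
#' @param label_col Label column name.
#' @return A cohort tibble with `n_total` rows (original row order kept).
#' @export
select_balanced_subset <- function(cohort, n_total, seed = 1L,
                                   label_col = "DEATH") {
  lab <- check_label(cohort, label_col)
  if (n_total %% 2 != 0) abort("n_total must be even for a balanced subset")
  half <- n_total / 2
  keep <- withr::with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      idx <- which(lab == cl)
      if (length(idx) < half) {
        abort(paste0("class ", cl, " has only ", length(idx),
                     " subjects; need ", half))
      }
      sample(idx, half)
    }))
  })
  cohort[sort(keep), , drop = FALSE]
}

#' Run the full parenclitic analysis and write its artifacts
#'
#' End-to-end driver: simulate (or accept) a cohort, run the leakage-free
#' two-scenario comparison, and additionally fit a whole-cohort descriptive
#' baseline on all survivors with its per-subject network features. Writes
#' `cohort.csv`, `features.csv`, `baseline.csv`, `report_raw.json`,
#' `report_enhanced.json`, `comparison.csv` and `manifest.json` (package
#' version, seeds, configuration hash, file list) into `output_dir`. Two
#' runs with equal configuration hashes produce byte-identical reports.
#'
#' @param cohort A cohort tibble, or a [synthetic_config()] to simulate
#'   from.
#' @param config A [classifier_config()].
#' @param output_dir Directory to write into (created if needed); `NULL`
#'   writes nothing.
#' @param write_networks Also write per-subject edge-list CSV and GraphML
#'   files under `output_dir/networks/` (off by default: one file pair per
#'   subject).
#' @param label_col Label column name.
#' @return A list with elements `cohort`, `comparison`, `baseline`,
#'   `features` and `manifest`, invisibly.
#' @export
run_pipeline <- function(cohort, config = classifier_config(),
                         output_dir = NULL, write_networks = FALSE,
                         label_col = "DEATH") {
  stopifnot(inherits(config, "classifier_config"))
  seed_used <- config$seed
  cohort_cfg <- NULL
  if (inherits(cohort, "synthetic_config")) {
    cohort_cfg <- cohort
    cohort <- generate_cohort(cohort_cfg)
  }
  cohort <- tibble::as_tibble(cohort)
  lab <- check_label(cohort, label_col)

  comparison <- run_comparison(cohort, config, label_col)

  # descriptive whole-cohort view (all survivors as baseline); CV numbers
  # above are the leakage-controlled ones
  feats <- feature_names_of(cohort, label_col)
  model <- fit_baseline(cohort[lab == 0L, , drop = FALSE],
                        feature_names = feats, label_col = label_col)
  nets <- compute_networks(cohort, model, label_col,
                           threshold = config$network_threshold)
  features <- featurize(nets)

  manifest <- list(
    package = "parenclitic",
    version = as.character(utils::packageVersion("parenclitic")),
    seed = seed_used,
    synthetic_seed = if (!is.null(cohort_cfg)) cohort_cfg$seed else NULL,
    config_hash = rlang::hash(list(cohort = cohort, config = config)),
    n_subjects = nrow(cohort), n_features = length(feats),
    scores = list(raw = comparison$raw$mean_score,
                  enhanced = comparison$enhanced$mean_score,
                  relative_error_reduction = comparison$relative_error_reduction))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(output_dir, "cohort.csv"))
    readr::write_csv(features, file.path(output_dir, "features.csv"))
    write_baseline_csv(model, file.path(output_dir, "baseline.csv"))
    for (scen in c("raw", "enhanced")) {
      rep <- comparison[[scen]]
      jsonlite::write_json(
        list(scenario = rep$scenario, fold_scores = rep$fold_scores,
             mean_score = rep$mean_score, error = rep$error,
             selected_features = rep$selected_features,
             selection_trace = rep$selection_trace,
             seed = seed_used, config_hash = manifest$config_hash),
        file.path(output_dir, paste0("report_", scen, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    readr::write_csv(tidy(comparison), file.path(output_dir, "comparison.csv"))
    files <- c("cohort.csv", "features.csv", "baseline.csv",
               "report_raw.json", "report_enhanced.json", "comparison.csv")
    if (write_networks) {
      netdir <- file.path(output_dir, "networks")
      dir.create(netdir, showWarnings = FALSE)
      for (net in nets) {
        write_network_csv(net, file.path(netdir, paste0(net$subject_id, ".csv")))
        write_network_graphml(net, file.path(netdir,
                                             paste0(net$subject_id, ".graphml")))
      }
      files <- c(files, "networks/")
    }
    manifest$files <- files
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(list(cohort = cohort, comparison = comparison, baseline = model,
                 features = features, manifest = manifest))
}
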