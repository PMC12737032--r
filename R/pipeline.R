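# End-to-end study orchestration: cohort in -> activity signals for every
# requested pipeline -> NPCRA indicators + sleep scores -> similarity
# matrices and dendrograms, with a manifest for replayability. Pooled
# ZCM/TAT thresholds are computed in a streaming first pass (running
# moments only), then recordings are regenerated/re-read in the second
# pass, so cohort memory stays flat.

#' Study configuration
#'
#' @param synthetic list of arguments for [synthetic_config()] (the
#'   synthetic cohort spec), or `NULL` when reading raw CSVs
#' @param raw_dir directory of raw CSVs (`timestamp_ms,x,y,z`), or `NULL`
#' @param n_subjects cohort size (synthetic input)
#' @param pipelines `"device_suite"` or a character vector of roster
#'   labels such as `"PIM(FMpre)"`
#' @param accel_schemes preprocessing schemes analysed directly as
#'   acceleration signals (1 s profiles), e.g. `c("ENMO", "FMpre")`
#' @param epoch_length epoch length, seconds
#' @param normalize mean-normalize series before L5/M10 (default TRUE)
#' @param threshold_basis `"pooled"` (SD rule over the whole cohort) or
#'   `"per_recording"`
#' @param sleep_algorithms subset of `c("masda", "vanhees")`
#' @param masda_threshold trend fraction for the activity scorer
#' @param spt_threshold z-angle SPT threshold for the acceleration scorer
#' @param calibrate apply [sphere_calibrate()] to each recording
#' @param out_dir output directory for result files, or `NULL`
#' @param seed study seed
#' @return object of class `study_config`
#' @export
study_config <- function(synthetic = list(), raw_dir = NULL,
                         n_subjects = 10,
                         pipelines = "device_suite",
                         accel_schemes = character(0),
                         epoch_length = 60, normalize = TRUE,
                         threshold_basis = c("pooled", "per_recording"),
                         sleep_algorithms = c("masda", "vanhees"),
                         masda_threshold = 0.25, spt_threshold = 0.4,
                         calibrate = FALSE,
                         out_dir = NULL, seed = 1L) {
  threshold_basis <- match.arg(threshold_basis)
  if (length(pipelines) == 0 && length(accel_schemes) == 0) {
    stop_config("select at least one pipeline")
  }
  structure(list(synthetic = synthetic, raw_dir = raw_dir,
                 n_subjects = n_subjects, pipelines = pipelines,
                 accel_schemes = accel_schemes,
                 epoch_length = epoch_length, normalize = normalize,
                 threshold_basis = threshold_basis,
                 sleep_algorithms = match.arg(sleep_algorithms,
                                              several.ok = TRUE),
                 masda_threshold = masda_threshold,
                 spt_threshold = spt_threshold,
                 calibrate = calibrate,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "study_config")
}

parse_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Z]+)\\(([A-Za-z]+)\\)$", label))[[1]]
  if (length(m) != 3) stop_config("cannot parse method label '", label, "'")
  list(metric = m[2], scheme = m[3])
}

resolve_pipelines <- function(config) {
  if (identical(config$pipelines, "device_suite")) {
    list(labels = c("PIM(FMpre)", "ZCM(FMpre)", "TAT(FMpre)", "PIM(ENMO)",
                    "AC", "MW"),
         device = c(AC = TRUE, MW = TRUE))
  } else {
    roster <- valid_combinations()$label
    bad <- setdiff(setdiff(config$pipelines, c("AC", "MW")), roster)
    if (length(bad)) {
      stop_config("unknown pipeline(s): ", paste(bad, collapse = ", "))
    }
    list(labels = config$pipelines)
  }
}

# schemes whose pooled SD the ZCM/TAT labels need
threshold_schemes <- function(labels) {
  labs <- grep("^(ZCM|TAT)\\(", labels, value = TRUE)
  unique(vapply(labs, function(l) parse_label(l)$scheme, character(1)))
}

study_recording <- function(config, i, cfgs) {
  rec <- if (!is.null(config$raw_dir)) {
    files <- sort(list.files(config$raw_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0) stop_config("no CSVs in ", config$raw_dir)
    regularize_timestamps(read_raw(files[i]))
  } else {
    generate_recording(cfgs[[i]])$recording
  }
  if (isTRUE(config$calibrate)) rec <- sphere_calibrate(rec)$recording
  rec
}

#' Run the full comparison study
#'
#' For every recording and pipeline: the activity series, its NPCRA
#' indicators and (optionally) its trend-threshold sleep score; plus the
#' acceleration-based sleep score and any direct acceleration-signal
#' NPCRA. Indicator tables then become SMAPE / window-overlap / IoU
#' similarity matrices with complete-linkage dendrograms. Identical
#' config + seed gives identical results.
#'
#' @param config a [study_config()]
#' @return list with `tables` (per-indicator subject x pipeline tables),
#'   `matrices`, `dendrograms`, `tst` (total sleep times, h), `npcra`
#'   (per subject x pipeline results), `truth` (synthetic ground truth),
#'   `manifest`
#' @export
run_study <- function(config) {
  pl <- resolve_pipelines(config)
  labels <- pl$labels
  n <- if (!is.null(config$raw_dir)) {
    length(list.files(config$raw_dir, pattern = "\\.csv$"))
  } else config$n_subjects
  if (n < 1) stop_config("empty cohort")

  cfgs <- NULL
  truth <- NULL
  if (is.null(config$raw_dir)) {
    base <- do.call(synthetic_config, config$synthetic)
    cfgs <- cohort_configs(base, config$n_subjects, config$seed)
    truth <- lapply(cfgs, function(cf) generate_truth_only(cf))
  }

  # ---- pass 1: pooled threshold moments ----------------------------------
  need_schemes <- threshold_schemes(labels)
  thresholds <- list()
  if (length(need_schemes) > 0 && config$threshold_basis == "pooled") {
    mom <- lapply(need_schemes, function(s) c(n = 0, s1 = 0, s2 = 0))
    names(mom) <- need_schemes
    for (i in seq_len(n)) {
      rec <- study_recording(config, i, cfgs)
      for (s in need_schemes) {
        v <- preprocess(rec, s)$values
        mom[[s]] <- mom[[s]] + c(length(v), sum(v), sum(v^2))
      }
    }
    for (s in need_schemes) {
      m <- mom[[s]]
      lvl <- sqrt((m["s2"] - m["s1"]^2 / m["n"]) / (m["n"] - 1))
      if (s == "UFM") lvl <- 1 + lvl
      thresholds[[s]] <- threshold_spec(unname(lvl), s, basis = "pooled")
    }
  }

  # ---- pass 2: per-subject computation -----------------------------------
  scalar_names <- c("L5val", "M10val", "RA", "IS", "IV")
  all_cols <- c(labels,
                if (length(config$accel_schemes))
                  paste0("ACC:", config$accel_schemes))
  tables <- lapply(scalar_names, function(ind) {
    matrix(NA_real_, n, length(all_cols),
           dimnames = list(NULL, all_cols))
  })
  names(tables) <- scalar_names
  onset_L5 <- onset_M10 <- matrix(NA_real_, n, length(all_cols),
                                  dimnames = list(NULL, all_cols))
  sleep_cols <- c(if ("masda" %in% config$sleep_algorithms) labels,
                  if ("vanhees" %in% config$sleep_algorithms) "vanhees(UFXYZ)")
  segments <- lapply(sleep_cols, function(i) vector("list", n))
  names(segments) <- sleep_cols
  tst <- matrix(NA_real_, n, length(sleep_cols),
                dimnames = list(NULL, sleep_cols))
  npcra_store <- vector("list", n)

  for (i in seq_len(n)) {
    rec <- study_recording(config, i, cfgs)
    series <- compute_pipeline_series(rec, labels, config$epoch_length,
                                      thresholds)
    res_i <- list()
    for (lab in labels) {
      r <- npcra_from_signal(series[[lab]], normalize = config$normalize)
      res_i[[lab]] <- r
      tables$L5val[i, lab] <- r$L5$mean_value
      tables$M10val[i, lab] <- r$M10$mean_value
      tables$RA[i, lab] <- r$RA
      tables$IS[i, lab] <- r$IS
      tables$IV[i, lab] <- r$IV
      onset_L5[i, lab] <- r$L5$onset_s
      onset_M10[i, lab] <- r$M10$onset_s
      if ("masda" %in% config$sleep_algorithms) {
        sc <- masda_score(series[[lab]],
                          threshold_frac = config$masda_threshold)
        segments[[lab]][[i]] <- sc$segments
        tst[i, lab] <- total_sleep_time(sc)
      }
    }
    for (s in config$accel_schemes) {
      sig <- preprocess(rec, s)
      if (s %in% c("FX", "FY", "FZ", "FMpost")) sig <- rectify(sig)
      r <- npcra_from_signal(sig, normalize = config$normalize)
      col <- paste0("ACC:", s)
      res_i[[col]] <- r
      tables$L5val[i, col] <- r$L5$mean_value
      tables$M10val[i, col] <- r$M10$mean_value
      tables$RA[i, col] <- r$RA
      tables$IS[i, col] <- r$IS
      tables$IV[i, col] <- r$IV
      onset_L5[i, col] <- r$L5$onset_s
      onset_M10[i, col] <- r$M10$onset_s
    }
    if ("vanhees" %in% config$sleep_algorithms) {
      sc <- vanhees_score(rec, spt_threshold = config$spt_threshold)
      segments[["vanhees(UFXYZ)"]][[i]] <- sc$segments
      tst[i, "vanhees(UFXYZ)"] <- total_sleep_time(sc)
    }
    npcra_store[[i]] <- res_i
  }

  # ---- matrices and dendrograms ------------------------------------------
  matrices <- list()
  dendrograms <- list()
  for (ind in scalar_names) {
    tab <- tables[[ind]][, colSums(is.na(tables[[ind]])) == 0, drop = FALSE]
    if (ncol(tab) >= 2) {
      matrices[[ind]] <- smape_matrix(tab)
      dendrograms[[ind]] <- pipeline_dendrogram(matrices[[ind]])
    }
  }
  if (ncol(onset_L5) >= 2) {
    matrices$L5onset <- overlap_matrix(onset_L5, 5)
    matrices$M10onset <- overlap_matrix(onset_M10, 10)
  }
  if (length(sleep_cols) >= 2) {
    matrices$sleep_IoU <- iou_matrix(segments)
    dendrograms$sleep_IoU <- pipeline_dendrogram(matrices$sleep_IoU)
  }

  manifest <- list(package = "actisig",
                   version = as.character(utils::packageVersion("actisig")),
                   config = unclass(config),
                   pipelines = labels,
                   thresholds = lapply(thresholds, unclass),
                   n_subjects = n)
  out <- list(tables = tables,
              onsets = list(L5 = onset_L5, M10 = onset_M10),
              matrices = matrices, dendrograms = dendrograms,
              tst = tst, segments = segments, npcra = npcra_store,
              truth = truth, manifest = manifest)
  if (!is.null(config$out_dir)) write_study(out, config$out_dir)
  invisible(out)
}

compute_pipeline_series <- function(rec, labels, epoch_length, thresholds) {
  sigs <- list()
  get_sig <- function(scheme) {
    if (is.null(sigs[[scheme]])) {
      sigs[[scheme]] <<- preprocess(rec, scheme)
    }
    sigs[[scheme]]
  }
  out <- list()
  for (lab in labels) {
    out[[lab]] <- if (lab == "AC") {
      emulate_ac(rec, epoch_length)
    } else if (lab == "MW") {
      emulate_mw(rec, epoch_length)
    } else {
      pl <- parse_label(lab)
      sig <- get_sig(pl$scheme)
      thr <- NULL
      if (pl$metric %in% c("ZCM", "TAT")) {
        thr <- thresholds[[pl$scheme]] %||%
          compute_threshold(sig, basis = "per_recording")
      }
      compute_activity(sig, pl$metric, epoch_length, threshold = thr)
    }
  }
  out
}

write_study <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$matrices)) {
    m <- res$matrices[[nm]]
    data.table::fwrite(data.table::data.table(pipeline = rownames(m),
                                              unclass(m)),
                       file.path(out_dir, paste0("matrix_", nm, ".csv")))
  }
  for (nm in names(res$dendrograms)) {
    writeLines(res$dendrograms[[nm]]$newick,
               file.path(out_dir, paste0("dendrogram_", nm, ".nwk")))
  }
  npcra_flat <- lapply(res$npcra, function(subj) {
    lapply(subj, function(r) {
      list(L5 = r$L5, M10 = r$M10, RA = r$RA, IS = r$IS, IV = r$IV,
           n_days = r$n_days_used)
    })
  })
  jsonlite::write_json(npcra_flat, file.path(out_dir, "npcra.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$tst) && ncol(res$tst) > 0) {
    data.table::fwrite(data.table::data.table(subject = seq_len(nrow(res$tst)),
                                              res$tst),
                       file.path(out_dir, "tst_hours.csv"))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
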