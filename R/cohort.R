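#' Load the bundled cohort table
#'
#' Reads a per-participant cohort file (comma-separated, header row, `#` comment
#' lines allowed) holding demographics, CMR volumes, maximum RV pressure, and the
#' per-patient mean maximum-principal RV stress/strain summaries of the 1G and 2G
#' model runs at the four cardiac time points (begin-filling, end-filling,
#' begin-ejection, end-ejection).
#'
#' The bundled fixture (`system.file("extdata", "tof_cohort.csv", package =
#' "ventmech2g")`) transcribes the published 18-participant cohort: 6 healthy
#' volunteers (HG) and 12 repaired Tetralogy-of-Fallot patients divided into
#' better (BG) and worse (WG) post-PVR outcome groups by the median change in
#' ejection fraction. Missing optional fields (indexed volumes and delta-EF for
#' healthy participants) are kept as `NA`, never zero-filled.
#'
#' @param path path to a delimited cohort file; defaults to the bundled fixture.
#' @return a `cohort` object: a data.frame with one row per participant and a
#'   `provenance` attribute naming the source file.
#' @export
load_cohort <- function(path = cohort_fixture_path()) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path)
  }
  dat <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                    strip.white = TRUE),
    error = function(e) stop("failed to parse cohort file: ", conditionMessage(e))
  )
  if (nrow(dat) == 0L) stop("cohort parse error: file has no participant rows")

  required <- c("id", "group", "sex", "age", "p_max_mmHg", "edv_cm3", "esv_cm3",
                "ef_pct", "delta_ef_pct",
                paste0("stress_1g_", c("bf", "be")),
                paste0("stress_2g_", c("bf", "ef", "be", "ee")),
                paste0("strain_1g_", c("bf", "be")),
                paste0("strain_2g_", c("bf", "ef", "be", "ee")))
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols)) {
    stop("cohort parse error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  num_cols <- setdiff(required, c("id", "group", "sex"))
  num_cols <- c(num_cols, intersect(c("edvi_ml_m2", "esvi_ml_m2"), names(dat)))
  for (cc in num_cols) {
    v <- dat[[cc]]
    if (is.character(v)) v[v == ""] <- NA
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(vn))
    if (length(bad)) {
      stop(sprintf("cohort parse error: row %d, column '%s': cannot parse '%s'",
                   bad[1], cc, as.character(v[bad[1]])))
    }
    dat[[cc]] <- vn
  }

  if (anyDuplicated(dat$id)) {
    stop("cohort validation error: duplicate participant id(s): ",
         paste(unique(dat$id[duplicated(dat$id)]), collapse = ", "))
  }
  if (!all(dat$group %in% c("HG", "BG", "WG"))) {
    stop("cohort validation error: group labels must be HG, BG or WG")
  }
  if (!all(dat$sex %in% c("M", "F"))) {
    stop("cohort validation error: sex must be M or F")
  }

  if (any(dat$esv_cm3 <= 0 | dat$edv_cm3 <= dat$esv_cm3)) {
    stop("cohort validation error: need 0 < ESV < EDV for every participant")
  }
  if (any(dat$ef_pct <= 0 | dat$ef_pct >= 100)) {
    stop("cohort validation error: EF must lie in (0, 100)")
  }
  if (any(abs(dat$stress_1g_bf - dat$stress_2g_bf) > 1e-9) ||
      any(abs(dat$strain_1g_bf - dat$strain_2g_bf) > 1e-9)) {
    stop("cohort validation error: 1G and 2G models must share the begin-filling state")
  }
  stress_cols <- grep("^stress_", names(dat), value = TRUE)
  strain_cols <- grep("^strain_", names(dat), value = TRUE)
  if (any(as.matrix(dat[stress_cols]) <= 0)) {
    stop("cohort validation error: stresses must be positive")
  }
  if (any(as.matrix(dat[strain_cols]) < 0)) {
    stop("cohort validation error: strains must be non-negative")
  }

  structure(dat, class = c("cohort", "data.frame"), provenance = path)
}

#' Path of the bundled 18-participant cohort fixture
#' @export
cohort_fixture_path <- function() {
  system.file("extdata", "tof_cohort.csv", package = "ventmech2g", mustWork = TRUE)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d participants (%s)\n", nrow(x),
              paste(sprintf("%d %s", table(x$group)[c("HG", "BG", "WG")],
                            c("HG", "BG", "WG")), collapse = ", ")))
  cat("Source:", attr(x, "provenance"), "\n")
  print.data.frame(utils::head(as.data.frame(x)[, 1:11]), row.names = FALSE)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Ejection fraction from end-diastolic and end-systolic volume
#'
#' EF (\%) = 100 (EDV - ESV) / EDV.
#'
#' @param edv end-diastolic volume (cm^3), must be positive.
#' @param esv end-systolic volume (cm^3), in [0, edv].
#' @return ejection fraction in percent.
#' @export
derive_ef <- function(edv, esv) {
  if (any(edv <= 0)) stop("derive_ef: EDV must be positive")
  if (any(esv < 0 | esv > edv)) stop("derive_ef: need 0 <= ESV <= EDV")
  100 * (edv - esv) / edv
}

#' Classify TOF participants into better/worse outcome groups
#'
#' Patients with post-PVR ejection-fraction change above the threshold are
#' labelled BG (better outcome), the rest WG. With `threshold = "median"` the
#' median of the TOF participants' delta-EF values is used (even n: midpoint of
#' the two central order statistics), which reproduces the published 6/6 split.
#'
#' @param cohort a `cohort` object.
#' @param threshold numeric cut (percent) or `"median"`.
#' @return named character vector of `"BG"`/`"WG"` labels for the TOF rows.
#' @export
classify_outcome <- function(cohort, threshold = "median") {
  tof <- cohort[cohort$group %in% c("BG", "WG"), , drop = FALSE]
  if (any(is.na(tof$delta_ef_pct))) {
    stop("classify_outcome: every TOF participant needs delta_ef")
  }
  thr <- if (identical(threshold, "median")) {
    stats::median(tof$delta_ef_pct)
  } else {
    as.numeric(threshold)
  }
  labels <- ifelse(tof$delta_ef_pct > thr, "BG", "WG")
  names(labels) <- tof$id
  attr(labels, "threshold") <- thr
  labels
}

#' Tidy long-format view of a cohort
#'
#' One row per participant x model generation x time point, with stress (kPa)
#' and strain (dimensionless) columns. 1G models only realise the begin-filling
#' and begin-ejection states, so their rows cover those two time points only.
#'
#' @param cohort a `cohort` object.
#' @return data.frame with columns id, group, generation, timepoint, stress, strain.
#' @export
cohort_long <- function(cohort) {
  tp1 <- c("bf", "be")
  tp2 <- c("bf", "ef", "be", "ee")
  rows <- list()
  for (gen in c("1g", "2g")) {
    tps <- if (gen == "1g") tp1 else tp2
    for (tp in tps) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = cohort$id, group = cohort$group,
        generation = toupper(gen), timepoint = toupper(tp),
        stress = cohort[[paste0("stress_", gen, "_", tp)]],
        strain = cohort[[paste0("strain_", gen, "_", tp)]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$timepoint <- factor(out$timepoint, levels = c("BF", "EF", "BE", "EE"))
  out[order(match(out$id, cohort$id), out$generation, out$timepoint), ]
}
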