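#' Read and write on-disk recording bundles
#'
#' A bundle is a directory holding one subject's coregistered recording as
#' plain text: `meta.json` (geometry, rates, subject id, seed, config echo),
#' `eeg.tsv.gz` (time + one column per channel, uV), `eye.tsv.gz` (time, xl,
#' yl, xr, yr, pl, pr; `NA` during dropout), `events.tsv` (kind, onset,
#' offset), `triggers.tsv` (time, code) and, for task sessions,
#' `trials.tsv`. Generated bundles additionally carry `ground_truth.tsv`
#' and `latent.tsv.gz`, which analysis stages ignore.
#'
#' @param rec A [coreg_recording()].
#' @param path Bundle directory (created if needed).
#' @param trials Optional trial table (tibble) for task sessions.
#' @param ground_truth,latent Optional generator-side tibbles.
#' @return `write_bundle()` returns `path` invisibly; `read_bundle()`
#'   returns a list with elements `recording`, `trials` (or `NULL`),
#'   `ground_truth`, `latent`.
#' @name bundle
NULL

# Serialize doubles with 17 significant digits so write/read round-trips
# are bit-identical (readr's default formatting drops the last bit).
write_tsv_precise <- function(tab, path) {
  tab <- tibble::as_tibble(tab)
  for (cc in names(tab)) {
    if (is.double(tab[[cc]])) {
      v <- sprintf("%.17g", tab[[cc]])
      v[is.na(tab[[cc]])] <- NA_character_
      tab[[cc]] <- v
    }
  }
  readr::write_tsv(tab, path, progress = FALSE)
}

#' @rdname bundle
#' @export
write_bundle <- function(rec, path, trials = NULL, ground_truth = NULL,
                         latent = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  eeg_rate <- rec$eeg[[1]]$rate
  eye_rate <- rec$eye$xl$rate
  meta <- list(
    subject = rec$meta$subject %||% "s01",
    seed = rec$meta$seed %||% NA,
    referenced = isTRUE(rec$meta$referenced),
    eeg_rate = eeg_rate, eye_rate = eye_rate,
    eeg_start = rec$eeg[[1]]$start, eye_start = rec$eye$xl$start,
    channels = names(rec$eeg),
    geometry = rec$geometry,
    config = rec$meta$config %||% NULL
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  eeg_tab <- c(list(time = ts_times(rec$eeg[[1]])),
               lapply(rec$eeg, function(ch) ch$values))
  write_tsv_precise(tibble::as_tibble(eeg_tab), file.path(path, "eeg.tsv.gz"))
  eye_cols <- c("xl", "yl", "xr", "yr", "pl", "pr")
  eye_tab <- c(list(time = ts_times(rec$eye$xl)),
               lapply(rec$eye[eye_cols], function(ch) ch$values))
  write_tsv_precise(tibble::as_tibble(eye_tab), file.path(path, "eye.tsv.gz"))

  ev <- if (length(rec$events) == 0L) {
    tibble::tibble(kind = character(0), onset = numeric(0), offset = numeric(0))
  } else {
    dplyr::bind_rows(lapply(names(rec$events), function(k) {
      tibble::tibble(kind = k, onset = rec$events[[k]]$onset,
                     offset = rec$events[[k]]$offset)
    }))
  }
  write_tsv_precise(ev, file.path(path, "events.tsv"))
  write_tsv_precise(rec$triggers, file.path(path, "triggers.tsv"))
  if (!is.null(trials)) {
    write_tsv_precise(trials, file.path(path, "trials.tsv"))
  }
  if (!is.null(ground_truth)) {
    write_tsv_precise(ground_truth, file.path(path, "ground_truth.tsv"))
  }
  if (!is.null(latent)) {
    write_tsv_precise(latent, file.path(path, "latent.tsv.gz"))
  }
  invisible(path)
}

# Read all columns as character and convert with R's own parser
# (strtod-backed, correctly rounded), so that 17-digit serialization
# round-trips bit-identically; vroom's fast float path can be 1 ulp off.
read_tsv_quiet <- function(file, ...) {
  tab <- readr::read_tsv(file, progress = FALSE, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"), ...)
  for (cc in names(tab)) {
    tab[[cc]] <- utils::type.convert(tab[[cc]], as.is = TRUE)
  }
  tab
}

require_columns <- function(tab, cols, file) {
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column %s", file, paste(missing, collapse = ", ")))
  }
}

#' @rdname bundle
#' @export
read_bundle <- function(path) {
  need_file <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("bundle is missing required file ", f)
    fp
  }
  meta <- jsonlite::read_json(need_file("meta.json"), simplifyVector = TRUE)

  eeg_tab <- read_tsv_quiet(need_file("eeg.tsv.gz"))
  require_columns(eeg_tab, c("time", meta$channels), "eeg.tsv.gz")
  if (is.unsorted(eeg_tab$time, strictly = TRUE)) {
    stop("eeg.tsv.gz: non-monotone timestamps")
  }
  eeg <- lapply(meta$channels, function(ch) {
    time_series(eeg_tab[[ch]], meta$eeg_rate, meta$eeg_start, "uV")
  })
  names(eeg) <- meta$channels

  eye_cols <- c("xl", "yl", "xr", "yr", "pl", "pr")
  eye_tab <- read_tsv_quiet(need_file("eye.tsv.gz"))
  require_columns(eye_tab, c("time", eye_cols), "eye.tsv.gz")
  if (is.unsorted(eye_tab$time, strictly = TRUE)) {
    stop("eye.tsv.gz: non-monotone timestamps")
  }
  units <- c(xl = "px", yl = "px", xr = "px", yr = "px", pl = "a.u.", pr = "a.u.")
  eye <- lapply(eye_cols, function(ch) {
    time_series(eye_tab[[ch]], meta$eye_rate, meta$eye_start, units[[ch]])
  })
  names(eye) <- eye_cols

  ev_tab <- read_tsv_quiet(need_file("events.tsv"))
  require_columns(ev_tab, c("kind", "onset", "offset"), "events.tsv")
  events <- lapply(split(ev_tab, ev_tab$kind), function(d) {
    interval_set(d$onset, d$offset, kind = d$kind)
  })

  tr_tab <- read_tsv_quiet(need_file("triggers.tsv"))
  require_columns(tr_tab, c("time", "code"), "triggers.tsv")

  geometry <- meta$geometry
  geometry$screen_px <- as.numeric(geometry$screen_px)

  rec <- coreg_recording(
    eeg = eeg, eye = eye, events = events, triggers = tr_tab,
    geometry = geometry,
    meta = list(subject = meta$subject, seed = meta$seed,
                referenced = isTRUE(meta$referenced), config = meta$config)
  )

  trials <- NULL
  if (file.exists(file.path(path, "trials.tsv"))) {
    trials <- read_tsv_quiet(file.path(path, "trials.tsv"))
    require_columns(trials, c("index", "task", "condition", "ref_on",
                              "act_on", "resp_on", "correct"), "trials.tsv")
  }
  ground_truth <- if (file.exists(file.path(path, "ground_truth.tsv"))) {
    read_tsv_quiet(file.path(path, "ground_truth.tsv"))
  }
  latent <- if (file.exists(file.path(path, "latent.tsv.gz"))) {
    read_tsv_quiet(file.path(path, "latent.tsv.gz"))
  }
  list(recording = rec, trials = trials, ground_truth = ground_truth,
       latent = latent)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
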