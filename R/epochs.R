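#' Epoched EEG container
#'
#' Bundles a 3-D voltage array (channel x sample x trial, microvolts) with its
#' sampling rate, the epoch time origin, and ordered channel labels from the
#' extended 10/20 system. All trials share one time axis; time is expressed in
#' milliseconds relative to the onset of the pre-cue that starts a trial.
#'
#' @param data numeric 3-D array, channel x sample x trial, in microvolts.
#' @param srate sampling rate in Hz.
#' @param t0_ms epoch time of the first sample (ms relative to pre-cue onset).
#' @param channels character vector of unique 10/20 channel labels, one per
#'   row of `data`.
#' @return An object of class `eeg_epochs`: a list with elements `data`,
#'   `srate`, `t0_ms`, `channels`.
#' @examples
#' e <- eeg_epochs(array(0, c(2, 100, 3)), srate = 500, t0_ms = -1000,
#'                 channels = c("PO7", "PO8"))
#' epoch_times(e)[1:4]
#' @export
eeg_epochs <- function(data, srate, t0_ms, channels) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_fmt("`data` must be a 3-D array (channel x sample x trial)")
  if (!is_count(srate)) stop_fmt("`srate` must be a positive number")
  if (!is.numeric(t0_ms) || length(t0_ms) != 1L)
    stop_fmt("`t0_ms` must be a single number")
  channels <- as.character(channels)
  if (length(channels) != dim(data)[1L])
    stop_fmt("%d channel labels for %d data rows", length(channels), dim(data)[1L])
  if (anyDuplicated(channels)) stop_fmt("channel labels must be unique")
  structure(list(data = data, srate = as.numeric(srate),
                 t0_ms = as.numeric(t0_ms), channels = channels),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d channels x %d samples x %d trials\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  srate %g Hz, epoch %g to %g ms\n", x$srate, x$t0_ms,
              x$t0_ms + (d[2L] - 1) * 1000 / x$srate))
  cat("  channels:", paste(utils::head(x$channels, 8), collapse = " "),
      if (d[1L] > 8) "..." else "", "\n")
  invisible(x)
}

#' @rdname eeg_epochs
#' @param epochs an `eeg_epochs` object.
#' @return `epoch_times()`: numeric vector of sample times in ms.
#' @export
epoch_times <- function(epochs) {
  epochs$t0_ms + (seq_len(dim(epochs$data)[2L]) - 1) * 1000 / epochs$srate
}

# Subset helpers keep metadata consistent.
subset_channels <- function(epochs, keep) {
  idx <- match(keep, epochs$channels)
  if (anyNA(idx)) stop_fmt("unknown channel(s): %s",
                           paste(keep[is.na(idx)], collapse = ", "))
  eeg_epochs(epochs$data[idx, , , drop = FALSE], epochs$srate, epochs$t0_ms,
             epochs$channels[idx])
}

subset_trials <- function(epochs, keep) {
  eeg_epochs(epochs$data[, , keep, drop = FALSE], epochs$srate, epochs$t0_ms,
             epochs$channels)
}

#' Write / read epoched EEG
#'
#' Epochs are stored as a flat little-endian binary array (`<name>.dat`,
#' channel index fastest, then sample, then trial) next to a human-readable
#' JSON sidecar (`<name>.json`) holding the sampling rate, epoch origin,
#' channel labels, dimensions and storage dtype. Channels are canonicalized
#' to alphabetical order on write; consumers address channels by label only.
#'
#' With the default `dtype = "float32"` values are stored in single
#' precision; a write/read cycle is then the identity for data already
#' representable in single precision (and for any subsequent cycles).
#' `dtype = "float64"` stores doubles bit-exactly.
#'
#' @param epochs an [eeg_epochs] object.
#' @param path file path; a trailing `.dat` or `.json` extension is stripped
#'   and both files are written next to each other.
#' @param overwrite logical; error if the target exists and this is `FALSE`.
#' @param dtype storage type, `"float32"` (default) or `"float64"`.
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()` returns
#'   an [eeg_epochs] object.
#' @export
write_epochs <- function(epochs, path, overwrite = FALSE,
                         dtype = c("float32", "float64")) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  dtype <- match.arg(dtype)
  base <- sub("\\.(dat|json)$", "", path)
  dat <- paste0(base, ".dat"); side <- paste0(base, ".json")
  if (!overwrite && (file.exists(dat) || file.exists(side)))
    stop_fmt("'%s' exists and overwrite = FALSE", dat)

  ord <- order(epochs$channels)
  data <- epochs$data[ord, , , drop = FALSE]
  d <- dim(data)
  meta <- list(format = "alphalat-epochs-v1",
               srate = epochs$srate, t0_ms = epochs$t0_ms,
               channels = epochs$channels[ord],
               n_channels = d[1L], n_samples = d[2L], n_trials = d[3L],
               dtype = dtype,
               layout = "little-endian; channel fastest, then sample, then trial")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  con <- file(dat, "wb"); on.exit(close(con))
  writeBin(as.numeric(data), con,
           size = if (dtype == "float32") 4L else 8L, endian = "little")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  base <- sub("\\.(dat|json)$", "", path)
  dat <- paste0(base, ".dat"); side <- paste0(base, ".json")
  if (!file.exists(side)) stop_fmt("sidecar '%s' not found", side)
  if (!file.exists(dat)) stop_fmt("data file '%s' not found", dat)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  need <- c("srate", "t0_ms", "channels", "n_channels", "n_samples",
            "n_trials", "dtype")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop_fmt("sidecar missing field(s): %s",
                             paste(miss, collapse = ", "))
  if (length(meta$channels) != meta$n_channels)
    stop_fmt("sidecar lists %d channels but n_channels = %d",
             length(meta$channels), meta$n_channels)
  n <- meta$n_channels * meta$n_samples * meta$n_trials
  size <- if (meta$dtype == "float32") 4L else 8L
  if (file.info(dat)$size != n * size)
    stop_fmt("'%s' has %d bytes; expected %d from sidecar dimensions",
             dat, file.info(dat)$size, n * size)
  con <- file(dat, "rb"); on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = size, endian = "little")
  eeg_epochs(array(x, c(meta$n_channels, meta$n_samples, meta$n_trials)),
             meta$srate, meta$t0_ms, meta$channels)
}

# ---- Trial tables ----------------------------------------------------------

.retrocue_tokens <- c("li", "re", "mi", "bei")
.probe_levels <- c("cued", "noncued", "new")
.response_levels <- c("yes", "no", "none")

#' Map retro-cue tokens to analysis conditions
#'
#' The four spoken retro-cue tokens are the first syllables of the German
#' words for left ("li"), right ("re"), middle ("mi") and both ("bei").
#' "li"/"re" keep the lateral item relevant (target-lateral), "mi" keeps the
#' central item (the lateral item becomes a distractor; distractor-lateral),
#' and "bei" keeps both (neutral).
#'
#' @param retrocue character vector of tokens (`li`, `re`, `mi`, `bei`).
#' @return character vector in `{target_lateral, distractor_lateral, neutral}`.
#' @export
retrocue_condition <- function(retrocue) {
  bad <- setdiff(unique(retrocue), .retrocue_tokens)
  if (length(bad)) stop_fmt("unknown retro-cue token(s): %s",
                            paste(bad, collapse = ", "))
  c(li = "target_lateral", re = "target_lateral",
    mi = "distractor_lateral", bei = "neutral")[retrocue]
}

#' Validate a trial table
#'
#' Checks column presence and category values of a per-trial design/behavior
#' table: `trial_id`, `block`, `precue_side` (left/right), `retrocue`
#' (li/re/mi/bei), `probe` (cued/noncued/new), `response` (yes/no/none),
#' `rt_ms`, `correct`, `rejected`. Enforces the design constraints that a
#' neutral ("bei") trial can never carry a non-cued probe (both items remain
#' relevant, so no item is "non-cued"), that the lateral target cues imply
#' their pre-cue side (`li` => left, `re` => right), and that a response time
#' is present exactly when a response was given.
#'
#' @param trials a data.frame.
#' @return the validated data.frame, invisibly typed.
#' @export
validate_trial_table <- function(trials) {
  need <- c("trial_id", "block", "precue_side", "retrocue", "probe",
            "response", "rt_ms", "correct", "rejected")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop_fmt("trial table missing column(s): %s",
                             paste(miss, collapse = ", "))
  if (nrow(trials) == 0L) return(invisible(trials))
  chk <- function(col, levels) {
    bad <- setdiff(unique(stats::na.omit(trials[[col]])), levels)
    if (length(bad)) stop_fmt("invalid %s value(s): %s", col,
                              paste(bad, collapse = ", "))
  }
  chk("precue_side", c("left", "right"))
  chk("retrocue", .retrocue_tokens)
  chk("probe", .probe_levels)
  chk("response", .response_levels)
  if (any(trials$retrocue == "bei" & trials$probe == "noncued"))
    stop_fmt(paste("neutral ('bei') trials cannot have probe = 'noncued':",
                   "with both items still relevant there is no non-cued item"))
  if (any(trials$retrocue == "li" & trials$precue_side != "left") ||
      any(trials$retrocue == "re" & trials$precue_side != "right"))
    stop_fmt("'li'/'re' retro-cues must match the pre-cued side")
  resp <- !is.na(trials$response) & trials$response != "none"
  if (any(resp & is.na(trials$rt_ms)))
    stop_fmt("rt_ms must be present when a response was given")
  if (any(!resp & !is.na(trials$rt_ms)))
    stop_fmt("rt_ms must be missing when response is 'none'")
  invisible(trials)
}

#' Read / write trial tables
#'
#' Trial tables are UTF-8 CSV files with a header row and the columns
#' documented in [validate_trial_table()]. An empty file yields an empty
#' (zero-row) typed table.
#'
#' @param path CSV file path.
#' @param trials a trial table data.frame.
#' @param overwrite logical; error if `path` exists and this is `FALSE`.
#' @return `read_trial_table()` returns a validated data.frame.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop_fmt("'%s' not found", path)
  if (file.info(path)$size == 0L) {
    x <- empty_trial_table()
  } else {
    x <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(x) == 0L) x <- empty_trial_table()
  }
  if (nrow(x)) {
    x$trial_id <- as.integer(x$trial_id)
    x$block <- as.integer(x$block)
    x$rt_ms <- as.numeric(x$rt_ms)
    x$correct <- as.logical(x$correct)
    x$rejected <- as.logical(x$rejected)
  }
  validate_trial_table(x)
  x
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(trials, path, overwrite = FALSE) {
  validate_trial_table(trials)
  if (!overwrite && file.exists(path))
    stop_fmt("'%s' exists and overwrite = FALSE", path)
  utils::write.csv(trials, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

empty_trial_table <- function() {
  data.frame(trial_id = integer(), block = integer(),
             precue_side = character(), retrocue = character(),
             probe = character(), response = character(),
             rt_ms = numeric(), correct = logical(), rejected = logical(),
             stringsAsFactors = FALSE)
}
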