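#' Names of the 65 per-channel features
#'
#' Catalogue order is fixed: 9 time-domain, 24 wavelet (4 features x
#' subbands D1..D5, A5), 28 spectral (4 features x 7 bands), 4 nonlinear.
#'
#' @return character vector of length 65.
#' @export
feature_names <- function() {
  time_n <- c("mean", "mean_square", "median", "peak_to_peak", "skewness",
              "kurtosis", "hjorth_activity", "hjorth_mobility",
              "hjorth_complexity")
  subbands <- c(paste0("D", 1:5), "A5")
  dwt_n <- as.vector(vapply(subbands, function(sb)
    paste0(c("relative_energy_", "shannon_entropy_", "max_energy_",
             "variance_"), sb), character(4)))
  band_n <- as.vector(vapply(eeg_bands()$band, function(bn)
    paste0(c("absolute_power_", "relative_power_", "max_power_",
             "peak_frequency_"), bn), character(4)))
  nl_n <- c("approx_entropy", "sample_entropy", "permutation_entropy",
            "correlation_dimension")
  c(time_n, dwt_n, band_n, nl_n)
}

# metadata columns of a feature table, in order
.meta_cols <- c("subject", "question", "scenario_type", "answer", "start",
                "duration")

#' Feature columns of a feature table
#'
#' @param tbl a feature table.
#' @return the non-metadata column names (channel.feature).
#' @export
feature_columns <- function(tbl) setdiff(names(tbl), .meta_cols)

# all 65 features for one channel vector
channel_features <- function(x, fs) {
  tf <- time_features(x)
  wf <- dwt_features(x, fs)
  sf <- spectral_features(x, fs)
  nf <- nonlinear_features(x)
  v <- c(tf, wf, sf, nf)
  attr(v, "degenerate") <- isTRUE(attr(tf, "degenerate")) ||
    isTRUE(attr(wf, "degenerate")) || isTRUE(attr(sf, "degenerate")) ||
    isTRUE(attr(nf, "degenerate"))
  v
}

#' Extract the epochs-by-features table
#'
#' One row per epoch; `n_channels x 65` feature columns named
#' `"<channel>.<feature>"` in stable montage-then-catalogue order, preceded
#' by the metadata columns (subject, question, scenario type, answer, epoch
#' start and duration). Extraction is fully deterministic. Channels whose
#' features degenerated (constant signal) are recorded in the table's
#' `degeneracies` attribute.
#'
#' @param epochs list of `eeg_epoch` objects sharing one channel set and
#'   sampling rate; may be empty (returns the empty table with full header).
#' @param channels channel subset to extract, default all channels of the
#'   first epoch.
#' @return a tibble (the feature table).
#' @export
extract_feature_table <- function(epochs, channels = NULL) {
  feats <- feature_names()
  if (length(epochs) == 0) {
    channels <- channels %||% montage_1020()$channel
    cols <- as.vector(outer(channels, feats, paste, sep = "."))
    empty <- c(
      stats::setNames(rep(list(character(0)), 4), .meta_cols[1:4]),
      stats::setNames(rep(list(numeric(0)), 2), .meta_cols[5:6]),
      stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    return(tibble::as_tibble(empty))
  }
  channels <- channels %||% epochs[[1]]$channels
  cols <- as.vector(outer(channels, feats, paste, sep = "."))
  degeneracies <- list()
  rows <- vector("list", length(epochs))
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    if (!all(channels %in% ep$channels))
      stop(sprintf("epoch %d lacks channels: %s", i,
                   paste(setdiff(channels, ep$channels), collapse = ", ")))
    vals <- matrix(NA_real_, length(channels), length(feats))
    for (ci in seq_along(channels)) {
      x <- ep$signal[match(channels[ci], ep$channels), ]
      v <- channel_features(x, ep$fs)
      if (isTRUE(attr(v, "degenerate")))
        degeneracies[[length(degeneracies) + 1]] <-
          tibble::tibble(epoch = i, channel = channels[ci])
      vals[ci, ] <- v
    }
    rows[[i]] <- tibble::tibble(
      subject = ep$subject %||% NA_character_,
      question = ep$question %||% NA_character_,
      scenario_type = ep$scenario_type %||% NA_character_,
      answer = ep$answer %||% NA_character_,
      start = ep$start, duration = ep$duration,
      !!!stats::setNames(as.list(as.vector(vals)), cols))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "degeneracies") <-
    if (length(degeneracies)) dplyr::bind_rows(degeneracies)
    else tibble::tibble(epoch = integer(0), channel = character(0))
  out
}

#' Fit a z-normalization scaler on training rows
#'
#' Per-feature-column mean and standard deviation learned from the training
#' table only; zero-variance columns are flagged and map to 0 when applied.
#' The rows the scaler saw are fingerprinted (`n_rows`, question IDs) so the
#' evaluation layer can audit that only training rows were used.
#'
#' @param train a non-empty feature table.
#' @return object of class `eeg_scaler`.
#' @export
fit_scaler <- function(train) {
  cols <- feature_columns(train)
  if (nrow(train) == 0) stop("cannot fit a scaler on an empty table")
  X <- as.matrix(train[cols])
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  structure(list(columns = cols, mean = mu, sd = sdv,
                 zero_var = cols[sdv < .Machine$double.eps],
                 n_rows = nrow(train),
                 questions_seen = sort(unique(train$question)),
                 fitted = TRUE),
            class = "eeg_scaler")
}

#' Apply a fitted scaler
#'
#' Transforms the feature columns to `(x - mean) / sd` using the training
#' parameters only; zero-variance training columns become all zeros.
#'
#' @param scaler an `eeg_scaler` from [fit_scaler()].
#' @param tbl a feature table with the same feature columns.
#' @return the transformed table.
#' @export
apply_scaler <- function(scaler, tbl) {
  if (!inherits(scaler, "eeg_scaler") || !isTRUE(scaler$fitted))
    stop("`scaler` is not a fitted eeg_scaler")
  if (!all(scaler$columns %in% names(tbl)))
    stop("table lacks columns the scaler was fitted on")
  X <- as.matrix(tbl[scaler$columns])
  sdv <- scaler$sd
  sdv[sdv < .Machine$double.eps] <- Inf  # zero-variance -> 0
  X <- sweep(sweep(X, 2, scaler$mean), 2, sdv, "/")
  tbl[scaler$columns] <- tibble::as_tibble(X)
  tbl
}

#' Write / read a feature table as CSV
#'
#' Values are written with 17 significant digits so a read round-trip is
#' bit-exact for doubles. A JSON sidecar (`<path>.json`) records the
#' metadata columns, channel set and feature catalogue.
#'
#' @param tbl feature table. @param path CSV path.
#' @return `path`, invisibly (`write_feature_table`); the re-read tibble
#'   (`read_feature_table`).
#' @export
write_feature_table <- function(tbl, path) {
  cols <- feature_columns(tbl)
  df <- as.data.frame(tbl)
  for (cl in names(df))
    if (is.double(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  chans <- unique(sub("\\..*$", "", cols))
  jsonlite::write_json(
    list(meta_columns = .meta_cols, channels = chans,
         features = feature_names(), n_rows = nrow(tbl)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  num_cols <- setdiff(names(df), .meta_cols[1:4])
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  tibble::as_tibble(df)
}
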