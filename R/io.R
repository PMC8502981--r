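#' Read and write sampled series
#'
#' Series are stored as tab-separated text with columns `time_ms`,
#' `voltage` and, for multivariate series, `stimulus`; a JSON sidecar
#' (`<path>.meta.json`) records the generating model, its parameters, the
#' integration step, the seed, and the affine rescale map when present.
#'
#' @param series A series tibble.
#' @param path Output file path (`.tsv`).
#' @param metadata Extra named metadata merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, metadata = list()) {
  check_series(series)
  df <- data.frame(time_ms = series$time, voltage = series$voltage)
  if ("stimulus" %in% names(series)) df$stimulus <- series$stimulus
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- c(list(model = attr(series, "model"), dt = attr(series, "dt"),
                 params = attr(series, "params"),
                 rescale_map = attr(series, "rescale_map")),
            metadata)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  s <- new_series(df$time_ms, df$voltage, df$stimulus)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    for (a in intersect(names(meta), c("model", "dt", "params",
                                       "rescale_map"))) {
      attr(s, a) <- meta[[a]]
    }
  }
  s
}

#' Serialize a dataset split
#'
#' Writes the three segments as series files plus a JSON sidecar holding
#' the beat onsets, segment beat counts, and the rescale map, so any run
#' can be reconstructed from its artifacts.
#'
#' @param split A `dataset_split`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_split <- function(split, dir) {
  stopifnot(inherits(split, "dataset_split"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_series(split$pre_train, file.path(dir, "pre_train.tsv"))
  write_series(split$train, file.path(dir, "train.tsv"))
  write_series(split$test, file.path(dir, "test.tsv"))
  jsonlite::write_json(
    list(beat_onsets = split$beat_onsets,
         n_warmup_beats = split$n_warmup_beats,
         n_train_beats = split$n_train_beats,
         n_test_beats = split$n_test_beats,
         rescale_map = split$rescale_map),
    file.path(dir, "split.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_split
#' @export
read_split <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "split.json"),
                              simplifyVector = TRUE)
  pre <- read_series(file.path(dir, "pre_train.tsv"))
  train <- read_series(file.path(dir, "train.tsv"))
  test <- read_series(file.path(dir, "test.tsv"))
  series <- bind_rows(pre, train, test)
  structure(
    list(pre_train = pre, train = train, test = test, series = series,
         beat_onsets = meta$beat_onsets,
         n_warmup_beats = meta$n_warmup_beats,
         n_train_beats = meta$n_train_beats,
         n_test_beats = meta$n_test_beats,
         rescale_map = as.list(meta$rescale_map)),
    class = "dataset_split"
  )
}
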