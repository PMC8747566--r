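#' Write a simulated session to a fixture directory
#'
#' Plain-text container: `eeg.tsv` and `emg.tsv` (channels x samples,
#' tab-separated) plus `meta.json` holding rates, channel names, the event
#' table and the ground-truth annotations (mixing columns, source labels,
#' class gains). Source activations are not written.
#'
#' @param sim session list from [simulate_session()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$eeg$data, file.path(dir, "eeg.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$emg$data, file.path(dir, "emg.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(
    rate = sim$eeg$rate,
    eeg_channels = sim$eeg$channel_names,
    emg_channels = sim$emg$channel_names,
    events = sim$eeg$events,
    truth = list(
      mixing_columns = sim$truth$mixing_columns,
      source_labels = sim$truth$source_labels,
      class_gains = sim$truth$class_gains,
      event_table = sim$truth$event_table,
      tasks = sim$truth$tasks,
      layout = sim$truth$layout
    )
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a session fixture directory
#'
#' @param dir directory written by [write_session()].
#' @return list with `eeg`, `emg` ([mc_recording()]s) and `truth`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  eeg <- as.matrix(utils::read.table(file.path(dir, "eeg.tsv"), sep = "\t"))
  emg <- as.matrix(utils::read.table(file.path(dir, "emg.tsv"), sep = "\t"))
  dimnames(eeg) <- NULL; dimnames(emg) <- NULL
  events <- tibble::as_tibble(meta$events)
  truth <- meta$truth
  truth$mixing_columns <- as.matrix(truth$mixing_columns)
  truth$class_gains <- as.matrix(truth$class_gains)
  truth$event_table <- tibble::as_tibble(truth$event_table)
  truth$layout <- tibble::as_tibble(truth$layout)
  list(
    eeg = mc_recording(eeg, meta$rate, meta$eeg_channels, events),
    emg = mc_recording(emg, meta$rate, meta$emg_channels, events),
    truth = truth
  )
}

#' Read an externally produced component label table
#'
#' Accepts a delimited text file with a `component` column and one
#' probability column per class (brain, muscle, eye, heart, line_noise,
#' channel_noise, other); rows are renormalized to sum to one, and the
#' winning class recomputed. The result plugs into
#' [select_top_components()] in place of [label_components()] output, so
#' probabilities exported from an external classifier can drive the
#' condition split.
#'
#' @param path file path (TSV/CSV, autodetected by extension).
#' @return label tibble matching the [label_components()] contract.
#' @export
read_label_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tbl <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep))
  stopifnot("component" %in% names(tbl), all(ic_classes %in% names(tbl)))
  P <- as.matrix(tbl[, ic_classes])
  P <- P / rowSums(P)
  tbl[, ic_classes] <- P
  tbl$winning_class <- ic_classes[max.col(P, ties.method = "first")]
  tbl
}

#' Export a decomposition as delimited text + JSON sidecar
#'
#' @param dec a `decomposition`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_decomposition <- function(dec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dec$unmixing, file.path(dir, "unmixing.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(dec$mixing, file.path(dir, "mixing.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(variance_share = dec$variance_share, rate = dec$rate,
         channel_names = dec$channel_names, center = dec$center),
    file.path(dir, "decomposition.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Write / read a feature table as delimited text
#'
#' Tab-separated values preceded by commented header lines (`#meta `)
#' carrying the per-column metadata (channel/component, band, bin) and the
#' approach tag, so a table round-trips with its provenance.
#'
#' @param table a `feature_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  meta <- attr(table, "column_meta")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#approach %s", attr(table, "approach")), con)
  for (cn in setdiff(names(meta), "column")) {
    writeLines(sprintf("#meta %s\t%s", cn,
                       paste(meta[[cn]], collapse = "\t")), con)
  }
  utils::write.table(as.data.frame(table), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                            sep = "\t", check.names = FALSE)
  tbl <- tibble::as_tibble(body)
  cols <- setdiff(names(tbl), c("trial", "task"))
  meta <- tibble::tibble(column = cols)
  for (h in grep("^#meta ", hdr, value = TRUE)) {
    parts <- strsplit(sub("^#meta ", "", h), "\t")[[1]]
    vals <- parts[-1]
    meta[[parts[1]]] <- utils::type.convert(vals, as.is = TRUE)
  }
  approach <- sub("^#approach ", "", grep("^#approach", hdr, value = TRUE)[1])
  new_feature_table(tbl, meta, approach)
}

#' Load a pipeline configuration from a JSON file
#'
#' The package ships its default analysis constants as
#' `inst/extdata/default_pipeline.json` — one source of truth for the many
#' numeric settings; any subset can be overridden in a user file.
#'
#' @param path JSON file; defaults to the shipped constants.
#' @return a [pipeline_config()].
#' @export
load_pipeline_config <- function(path = system.file("extdata",
                                                    "default_pipeline.json",
                                                    package = "eegdecode")) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

#' Minimal BrainVision reader
#'
#' Parses a BrainVision header (`.vhdr`), marker (`.vmrk`) and data file
#' into a [mc_recording()]. Supports multiplexed binary IEEE float 32 /
#' int 16 and vectorized/multiplexed ASCII data, which covers the common
#' export variants. Channel resolutions are applied; marker positions are
#' converted to 0-based sample indices.
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return a [mc_recording()].
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  get_val <- function(key) {
    m <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (length(m) == 0) return(NULL)
    sub(paste0("^", key, "="), "", m[1])
  }
  data_file <- file.path(dirname(vhdr), get_val("DataFile"))
  marker_file <- get_val("MarkerFile")
  n_ch <- as.integer(get_val("NumberOfChannels"))
  interval_us <- as.numeric(get_val("SamplingInterval"))
  rate <- 1e6 / interval_us
  fmt <- toupper(get_val("DataFormat") %||% "BINARY")
  orient <- toupper(get_val("DataOrientation") %||% "MULTIPLEXED")
  binfmt <- toupper(get_val("BinaryFormat") %||% "IEEE_FLOAT_32")

  ch_lines <- grep("^Ch\\d+=", lines, value = TRUE)[seq_len(n_ch)]
  ch_parts <- strsplit(sub("^Ch\\d+=", "", ch_lines), ",")
  ch_names <- vapply(ch_parts, `[[`, character(1), 1)
  ch_res <- vapply(ch_parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3])); if (is.na(r) || r == 0) 1 else r
  }, numeric(1))

  if (fmt == "BINARY") {
    sz <- file.info(data_file)$size
    if (binfmt == "IEEE_FLOAT_32") {
      raw_v <- readBin(data_file, "numeric", n = sz / 4, size = 4,
                       endian = "little")
    } else if (binfmt == "INT_16") {
      raw_v <- readBin(data_file, "integer", n = sz / 2, size = 2,
                       signed = TRUE, endian = "little")
    } else stop("unsupported BinaryFormat: ", binfmt)
  } else {
    raw_v <- scan(data_file, quiet = TRUE)
  }
  n_samp <- length(raw_v) %/% n_ch
  raw_v <- raw_v[seq_len(n_samp * n_ch)]
  data <- if (orient == "MULTIPLEXED") {
    matrix(raw_v, nrow = n_ch)
  } else {
    t(matrix(raw_v, ncol = n_ch))
  }
  data <- data * ch_res

  events <- tibble::tibble(code = character(), sample = integer())
  if (!is.null(marker_file)) {
    mpath <- file.path(dirname(vhdr), marker_file)
    if (file.exists(mpath)) {
      mlines <- grep("^Mk\\d+=", readLines(mpath, warn = FALSE), value = TRUE)
      parts <- strsplit(sub("^Mk\\d+=", "", mlines), ",")
      keep <- vapply(parts, length, integer(1)) >= 3
      parts <- parts[keep]
      events <- tibble::tibble(
        code = vapply(parts, `[[`, character(1), 2),
        sample = vapply(parts, function(p) as.integer(p[3]) - 1L, integer(1)))
    }
  }
  mc_recording(data, rate, ch_names, events)
}
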