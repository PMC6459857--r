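#' Write / read a photon stream container
#'
#' Streams are stored in a plain-text container patterned on the
#' hierarchical photon-HDF5 layout: a YAML header holding the
#' `photon_data`/`setup` metadata groups, a `---` separator, then the photon
#' table as TSV (`macro_time_s`, `micro_time_ns`, `channel`, and the
#' ground-truth columns `molecule`/`state` when present).  The round trip is
#' lossless: macro times are written at full double precision.
#'
#' @param stream A `photon_stream`.
#' @param path Output path (conventionally `.smstream`).
#' @return `write_stream()` the path, invisibly; `read_stream()` a
#'   `photon_stream`.
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "photon_stream"))
  meta <- attr(stream, "metadata")
  header <- list(
    format = "smdyn-photon-stream",
    version = "1.0",
    photon_data = list(
      n_photons = nrow(stream),
      timestamps_unit_s = 1,
      microtimes_unit_ns = 1,
      measurement_type = "smMFD-4ch"),
    setup = meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(yaml::as.yaml(header), con)
  writeLines("---", con)
  df <- as.data.frame(stream)
  names(df)[names(df) == "macro_time"] <- "macro_time_s"
  names(df)[names(df) == "micro_time"] <- "micro_time_ns"
  df$channel <- as.character(df$channel)
  # full precision text round trip
  cols <- lapply(df, function(x)
    if (is.double(x)) sprintf("%.17g", x) else as.character(x))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  lines <- readLines(path)
  sep <- which(lines == "---")[1]
  if (is.na(sep)) stop("malformed stream container: missing '---' separator")
  header <- yaml::yaml.load(paste(lines[seq_len(sep - 1)], collapse = "\n"))
  if (is.null(header$format) || header$format != "smdyn-photon-stream")
    stop("malformed stream container: missing field 'format'")
  if (is.null(header$photon_data))
    stop("malformed stream container: missing field 'photon_data'")
  body <- lines[(sep + 1):length(lines)]
  body <- body[nzchar(body)]
  if (length(body) < 1)
    stop("malformed stream container: missing photon table header")
  df <- if (length(body) == 1) {
    nm <- strsplit(body, "\t")[[1]]
    as.data.frame(stats::setNames(replicate(length(nm), numeric(0),
                                            simplify = FALSE), nm))
  } else {
    data.table::fread(text = body, sep = "\t", data.table = FALSE)
  }
  need <- c("macro_time_s", "micro_time_ns", "channel")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed stream container: missing field(s): ",
         paste(miss, collapse = ", "))
  names(df)[match(c("macro_time_s", "micro_time_ns"), names(df))] <-
    c("macro_time", "micro_time")
  meta <- header$setup
  if (!is.null(meta$background_khz))
    meta$background_khz <- as.numeric(unlist(meta$background_khz))
  new_photon_stream(tibble::as_tibble(df), metadata = meta)
}
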