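# Event-list files: tab-separated text with a small commented header
# carrying units and the generation fingerprint. Columns:
# x1 y1 z1 E1 x2 y2 z2 E2 [label truth_E0 truth_x truth_y truth_z bg_kind]
# Lengths in mm, energies in MeV. Truth columns may be absent
# (experimental-style input); in that case selection metrics refuse the
# list cleanly.

.mandatory_cols <- c("x1", "y1", "z1", "E1", "x2", "y2", "z2", "E2")
.truth_cols <- c("label", "truth_E0", "truth_x", "truth_y", "truth_z",
                 "bg_kind")

.fmt_num <- function(x) {
  out <- sprintf("%.10g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write / read a coincidence event list
#'
#' Plain-text tab-separated serialization with a commented header
#' (format version, units, config hash, seed). `read_events` validates
#' the schema: mandatory position/energy columns present, energies
#' finite and positive; violations raise a `pg_schema_error` naming the
#' first offending row. Writing the result of `read_events` reproduces
#' the file byte for byte.
#'
#' @param events event data.frame.
#' @param path file path.
#' @return `read_events` returns the event data.frame with attribute
#'   `truth_available`; `write_events` returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  cols <- intersect(c(.mandatory_cols, .truth_cols), names(events))
  con <- file(path, "w")
  on.exit(close(con))
  hash <- attr(events, "config_hash")
  if (is.null(hash)) {
    cfg <- attr(events, "config")
    hash <- if (is.null(cfg)) "none" else config_hash(cfg)
  }
  seed <- attr(events, "seed")
  writeLines(c(
    "# pgcc event list v1",
    "# units: positions mm, energies MeV",
    paste0("# config_hash: ", hash),
    paste0("# seed: ", if (is.null(seed)) "NA" else seed)
  ), con)
  writeLines(paste(cols, collapse = "\t"), con)
  body <- vapply(seq_len(nrow(events)), function(i) {
    paste(vapply(cols, function(cn) {
      v <- events[[cn]][i]
      if (is.numeric(v)) .fmt_num(v) else ifelse(is.na(v), "NA", as.character(v))
    }, character(1)), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  events <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                       stringsAsFactors = FALSE, na.strings = "NA")
  missing_cols <- setdiff(.mandatory_cols, names(events))
  if (length(missing_cols))
    pg_schema_error(paste0("missing mandatory column(s): ",
                           paste(missing_cols, collapse = ", ")))
  for (cn in c("E1", "E2")) {
    bad <- which(!is.finite(events[[cn]]) | events[[cn]] <= 0)
    if (length(bad))
      pg_schema_error(paste0("non-positive or non-finite ", cn, " at row ",
                             bad[1]))
  }
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  hash <- sub("^# config_hash: ", "", grep("^# config_hash:", hdr, value = TRUE))
  if (length(hash)) attr(events, "config_hash") <- hash
  seed_line <- sub("^# seed: ", "", grep("^# seed:", hdr, value = TRUE))
  if (length(seed_line) && seed_line != "NA")
    attr(events, "seed") <- as.integer(seed_line)
  attr(events, "truth_available") <-
    "label" %in% names(events) && !anyNA(events$label)
  events
}
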