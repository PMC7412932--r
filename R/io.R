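# File I/O: plain-text epoch containers (TSV body + JSON metadata header)
# and similarity/ranking tables. Numeric samples are written with %.17g so
# a write/read round trip is bit-exact for doubles.

EPOCH_SCHEMA_VERSION <- "1"

#' Write an epoch set to a plain-text container
#'
#' The container is a single TSV file whose first line is a `#`-prefixed
#' JSON metadata header (schema version, subject, rate, window, channels),
#' followed by one row per (epoch, channel) with the label, symbol,
#' optional block/trial/round indices and the sample values. Sample values
#' are formatted with 17 significant digits, so the round trip through
#' [read_epochs()] is lossless.
#'
#' @param epochs An [epoch_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  meta <- list(
    format = "rsvpcar-epochs", schema_version = EPOCH_SCHEMA_VERSION,
    subject_id = epochs$subject_id, rate = epochs$rate,
    window = epochs$window, channel_names = epochs$channel_names,
    n_epochs = d[1L], n_channels = d[2L], n_samples = d[3L],
    has_structure = !is.null(epochs$block))
  header <- paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  # body: one row per (epoch, channel); epoch index varies slowest
  idx_e <- rep(seq_len(d[1L]), each = d[2L])
  idx_c <- rep(seq_len(d[2L]), d[1L])
  # flatten to (epoch*channel) x samples with epoch-major ordering
  flat <- matrix(aperm(epochs$data, c(2L, 1L, 3L)), nrow = d[1L] * d[2L])
  chr <- matrix(num_chr(flat), nrow = nrow(flat))
  lead <- data.frame(
    epoch = idx_e, channel = epochs$channel_names[idx_c],
    label = epochs$labels[idx_e], symbol = epochs$symbols[idx_e],
    epoch_id = epochs$epoch_ids[idx_e], stringsAsFactors = FALSE)
  if (!is.null(epochs$block)) {
    lead$block <- epochs$block[idx_e]
    lead$trial <- epochs$trial[idx_e]
    lead$round <- epochs$round[idx_e]
  }
  cols <- c(names(lead), sprintf("s%d", seq_len(d[3L])))
  body <- do.call(paste, c(unname(lead), split(chr, col(chr)), sep = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, paste(cols, collapse = "\t"), body), con)
  invisible(path)
}

#' Read an epoch set from a plain-text container
#'
#' @param path Path written by [write_epochs()].
#' @return An [epoch_set()] equal to the one written (bitwise for sample
#'   values, exact for labels/symbols/metadata).
#' @export
read_epochs <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#"))
    stop2("not an epoch container: missing JSON metadata header")
  meta <- jsonlite::fromJSON(sub("^#", "", first))
  if (!identical(meta$format, "rsvpcar-epochs"))
    stop2("not an epoch container (format: ", meta$format %||% "unknown", ")")
  if (!identical(as.character(meta$schema_version), EPOCH_SCHEMA_VERSION))
    stop2(sprintf("schema version mismatch: file has %s, reader expects %s",
                  meta$schema_version, EPOCH_SCHEMA_VERSION))
  tab <- data.table::fread(path, skip = 1L, sep = "\t", header = TRUE,
                           data.table = FALSE)
  req <- c("epoch", "channel", "label", "symbol")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop2("epoch container lacks column(s): ", paste(miss, collapse = ", "))
  ne <- meta$n_epochs; nc <- meta$n_channels; ns <- meta$n_samples
  if (nrow(tab) != ne * nc)
    stop2(sprintf("container has %d rows, expected %d", nrow(tab), ne * nc))
  scols <- sprintf("s%d", seq_len(ns))
  flat <- as.matrix(tab[, scols, drop = FALSE])
  arr <- aperm(array(t(flat), c(ns, nc, ne)), c(3L, 2L, 1L))
  first_of_epoch <- match(seq_len(ne), tab$epoch)
  has_struct <- isTRUE(meta$has_structure) && all(c("block", "trial", "round")
                                                  %in% names(tab))
  epoch_set(
    arr,
    labels = tab$label[first_of_epoch],
    symbols = tab$symbol[first_of_epoch],
    rate = meta$rate, window = as.numeric(meta$window),
    channel_names = as.character(meta$channel_names),
    subject_id = meta$subject_id,
    block = if (has_struct) tab$block[first_of_epoch],
    trial = if (has_struct) tab$trial[first_of_epoch],
    round = if (has_struct) tab$round[first_of_epoch],
    epoch_ids = if ("epoch_id" %in% names(tab)) tab$epoch_id[first_of_epoch])
}

#' Write a similarity matrix (or ranking) as TSV with a JSON header
#'
#' @param sim A `similarity_matrix` or `subject_ranking`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(sim, "similarity_matrix")) {
    meta <- list(format = "rsvpcar-similarity", metric = sim$metric,
                 vectorization = sim$vectorization)
    writeLines(paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
    writeLines(paste(c("subject_id", sim$subject_ids), collapse = "\t"), con)
    for (i in seq_along(sim$subject_ids))
      writeLines(paste(c(sim$subject_ids[i], num_chr(sim$values[i, ])),
                       collapse = "\t"), con)
  } else if (inherits(sim, "subject_ranking")) {
    meta <- list(format = "rsvpcar-ranking", test_subject = sim$test_subject,
                 metric = sim$metric, segment = sim$segment)
    writeLines(paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
    writeLines("subject_id\tr", con)
    writeLines(paste(sim$ranked_donors$subject_id,
                     num_chr(sim$ranked_donors$r), sep = "\t"), con)
  } else stop2("unsupported object for write_similarity()")
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity()]
#'
#' @param path File path.
#' @return A `similarity_matrix`.
#' @export
read_similarity <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- jsonlite::fromJSON(sub("^#", "", first))
  if (!identical(meta$format, "rsvpcar-similarity"))
    stop2("not a similarity matrix file")
  tab <- utils::read.delim(path, skip = 1L, check.names = FALSE)
  ids <- tab$subject_id
  v <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(v) <- list(ids, colnames(v))
  structure(list(subject_ids = ids, values = v, metric = meta$metric,
                 vectorization = meta$vectorization),
            class = "similarity_matrix")
}
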