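#' Construct a frequency contour
#'
#' A frequency contour is the time series of a syllable's dominant frequency,
#' sampled uniformly every `hop` seconds. Frequencies are stored in kHz.
#'
#' @param freq numeric vector of frequency samples in kHz (length >= 2, all
#'   positive and finite).
#' @param hop sampling interval of the contour in seconds (> 0).
#' @param syllable_id identifier of the syllable (coerced to character).
#' @param individual_id identifier of the emitting individual.
#' @param group group label of the individual (e.g. `"WT"`, `"HT"`).
#' @param start_time onset of the syllable in the source recording, seconds.
#' @param clipped logical; `TRUE` marks a syllable whose recording exceeded
#'   the amplitude limit of the system. Clipped syllables are carried through
#'   I/O but excluded from analysis.
#'
#' @return An object of class `usv_contour`.
#' @export
frequency_contour <- function(freq, hop, syllable_id, individual_id = "unknown",
                              group = "unknown", start_time = 0,
                              clipped = FALSE) {
  freq <- as.numeric(freq)
  if (length(freq) < 2L)
    stop("a frequency contour needs at least 2 samples")
  if (any(!is.finite(freq)) || any(freq <= 0))
    stop("contour frequencies must be finite and > 0 kHz")
  if (!is.numeric(hop) || length(hop) != 1L || hop <= 0)
    stop("'hop' must be a single positive number (seconds)")
  if (start_time < 0) stop("'start_time' must be >= 0")
  structure(list(
    syllable_id   = as.character(syllable_id),
    individual_id = as.character(individual_id),
    group         = as.character(group),
    start_time    = as.numeric(start_time),
    hop           = as.numeric(hop),
    freq          = freq,
    clipped       = isTRUE(clipped)
  ), class = "usv_contour")
}

#' @export
print.usv_contour <- function(x, ...) {
  cat(sprintf("<usv_contour %s> individual %s (%s), %d samples @ %.3f ms, %.1f-%.1f kHz%s\n",
              x$syllable_id, x$individual_id, x$group, length(x$freq),
              x$hop * 1000, min(x$freq), max(x$freq),
              if (x$clipped) ", CLIPPED" else ""))
  invisible(x)
}

#' Duration of a contour in seconds
#'
#' Fence-post convention: `(n - 1) * hop` for `n` samples.
#' @param c a `usv_contour`.
#' @return duration in seconds.
#' @export
contour_duration <- function(c) (length(c$freq) - 1L) * c$hop

#' Assemble a contour collection
#'
#' A collection is an ordered list of contours with a common hop and
#' consistent individual-to-group metadata. Row/column `i` of any matrix
#' derived from a collection refers to contour `i` in this order.
#'
#' @param contours list of `usv_contour` objects.
#' @return An object of class `usv_collection`.
#' @export
contour_collection <- function(contours) {
  if (!is.list(contours))
    stop("'contours' must be a list of usv_contour objects")
  ok <- vapply(contours, inherits, logical(1), what = "usv_contour")
  if (length(contours) && !all(ok))
    stop("all elements must be usv_contour objects")
  if (length(contours)) {
    hops <- vapply(contours, `[[`, numeric(1), "hop")
    if (diff(range(hops)) > 1e-12)
      stop("mixed contour hops in collection; resample to a common hop first ",
           "(see resample_collection())")
    ind <- vapply(contours, `[[`, character(1), "individual_id")
    grp <- vapply(contours, `[[`, character(1), "group")
    map <- tapply(grp, ind, function(g) length(unique(g)))
    if (any(map > 1L))
      stop("individual(s) assigned to more than one group: ",
           paste(names(map)[map > 1L], collapse = ", "))
  }
  structure(list(contours = contours), class = "usv_collection")
}

#' @export
length.usv_collection <- function(x) length(x$contours)

#' @export
print.usv_collection <- function(x, ...) {
  n <- length(x$contours)
  cat(sprintf("<usv_collection> %d contours", n))
  if (n) {
    tab <- table(groups(x))
    cat(";", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "))
    cat(sprintf("; %d clipped", sum(clipped_flags(x))))
  }
  cat("\n")
  invisible(x)
}

#' Metadata accessors for a collection
#'
#' @param x a `usv_collection`.
#' @return `groups()` the per-contour group labels; `individuals()` the
#'   per-contour individual ids; `individual_groups()` the named mapping
#'   individual -> group; `clipped_flags()` the per-contour clipped flags;
#'   `syllable_ids()` the per-contour syllable ids.
#' @export
groups <- function(x) vapply(x$contours, `[[`, character(1), "group")

#' @rdname groups
#' @export
individuals <- function(x) vapply(x$contours, `[[`, character(1), "individual_id")

#' @rdname groups
#' @export
individual_groups <- function(x) {
  ind <- individuals(x); grp <- groups(x)
  out <- grp[!duplicated(ind)]
  names(out) <- ind[!duplicated(ind)]
  out
}

#' @rdname groups
#' @export
clipped_flags <- function(x) vapply(x$contours, `[[`, logical(1), "clipped")

#' @rdname groups
#' @export
syllable_ids <- function(x) vapply(x$contours, `[[`, character(1), "syllable_id")

#' Drop clipped contours from a collection
#'
#' Syllables whose recording clipped are excluded from all analyses; this
#' preserves the relative order of the remaining contours.
#' @param x a `usv_collection`.
#' @return a `usv_collection` without clipped contours.
#' @export
drop_clipped <- function(x) {
  contour_collection(x$contours[!clipped_flags(x)])
}

#' Convert a collection to/from long-form tabular data
#'
#' The interchange format is one long-form table with columns
#' `syllable_id, individual_id, group, sample_index, time_s, freq_khz,
#' clipped`; `sample_index` is 0-based and `time_s = start_time +
#' sample_index * hop`.
#'
#' @param x a `usv_collection`.
#' @return `as.data.frame()` the long-form table; `collection_from_df()` the
#'   collection rebuilt from such a table.
#' @export
as.data.frame.usv_collection <- function(x, ...) {
  if (!length(x$contours))
    return(data.frame(syllable_id = character(), individual_id = character(),
                      group = character(), sample_index = integer(),
                      time_s = numeric(), freq_khz = numeric(),
                      clipped = logical()))
  do.call(rbind, lapply(x$contours, function(cc) {
    n <- length(cc$freq)
    data.frame(syllable_id = cc$syllable_id, individual_id = cc$individual_id,
               group = cc$group, sample_index = seq_len(n) - 1L,
               time_s = cc$start_time + (seq_len(n) - 1L) * cc$hop,
               freq_khz = cc$freq, clipped = cc$clipped)
  }))
}

#' @rdname as.data.frame.usv_collection
#' @param df a long-form contour data.frame.
#' @export
collection_from_df <- function(df) {
  req <- c("syllable_id", "individual_id", "group", "sample_index",
           "time_s", "freq_khz", "clipped")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!nrow(df)) stop("contour table is empty (no syllables)")
  bad <- !is.finite(df$freq_khz) | !is.finite(df$time_s)
  if (any(bad))
    stop("malformed row(s) (non-finite time or frequency) at table line(s): ",
         paste(head(which(bad), 5L), collapse = ", "))
  ids <- unique(df$syllable_id)
  contours <- lapply(ids, function(id) {
    d <- df[df$syllable_id == id, , drop = FALSE]
    d <- d[order(d$sample_index), , drop = FALSE]
    if (nrow(d) < 2L)
      stop("syllable ", id, " has fewer than 2 samples")
    hop <- diff(d$time_s[1:2])
    if (nrow(d) > 2L && max(abs(diff(d$time_s) - hop)) > 1e-9)
      stop("syllable ", id, " is not uniformly sampled")
    frequency_contour(d$freq_khz, hop = hop, syllable_id = id,
                      individual_id = d$individual_id[1],
                      group = d$group[1], start_time = d$time_s[1],
                      clipped = isTRUE(as.logical(d$clipped[1])))
  })
  hops <- vapply(contours, `[[`, numeric(1), "hop")
  if (diff(range(hops)) > 1e-9)
    stop("mixed hop values across syllables; resample to a common hop ",
         "(resampling-required)")
  contour_collection(contours)
}

#' Read / write contour collections
#'
#' Two equivalent on-disk layouts are supported: `"csv"`, the long-form
#' table (header required), and `"json"`, a list of syllable records each
#' carrying a frequency array.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; the default `"auto"` picks by file
#'   extension.
#' @return a `usv_collection`.
#' @export
read_contours <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    collection_from_df(df)
  } else {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    if (!length(recs)) stop("contour file is empty (no syllables)")
    contour_collection(lapply(recs, function(r)
      frequency_contour(unlist(r$freq_khz), hop = r$hop_s,
                        syllable_id = r$syllable_id,
                        individual_id = r$individual_id, group = r$group,
                        start_time = r$start_time_s,
                        clipped = isTRUE(r$clipped))))
  }
}

#' @rdname read_contours
#' @param x a `usv_collection` to write.
#' @export
write_contours <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    write.csv(as.data.frame(x), path, row.names = FALSE)
  } else {
    recs <- lapply(x$contours, function(cc)
      list(syllable_id = cc$syllable_id, individual_id = cc$individual_id,
           group = cc$group, start_time_s = cc$start_time, hop_s = cc$hop,
           clipped = cc$clipped, freq_khz = cc$freq))
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Resample a contour onto a new hop
#'
#' Linear interpolation of the frequency trajectory onto a uniform grid with
#' spacing `hop`, spanning the original duration. The last sample is placed
#' at the original end time, so duration is preserved to within one hop.
#'
#' @param c a `usv_contour`.
#' @param hop new sampling interval, seconds.
#' @return a resampled `usv_contour`.
#' @export
resample_contour <- function(c, hop) {
  if (hop <= 0) stop("'hop' must be > 0")
  if (abs(hop - c$hop) < 1e-15) return(c)
  dur <- contour_duration(c)
  n_new <- floor(dur / hop + 1e-9) + 1L
  if (n_new < 2L)
    stop("contour too short for requested hop (fewer than 2 samples)")
  t_old <- (seq_along(c$freq) - 1L) * c$hop
  t_new <- (seq_len(n_new) - 1L) * hop
  f_new <- approx(t_old, c$freq, xout = pmin(t_new, dur))$y
  frequency_contour(f_new, hop = hop, syllable_id = c$syllable_id,
                    individual_id = c$individual_id, group = c$group,
                    start_time = c$start_time, clipped = c$clipped)
}

#' @rdname resample_contour
#' @param x a `usv_collection`.
#' @export
resample_collection <- function(x, hop) {
  contour_collection(lapply(x$contours, resample_contour, hop = hop))
}
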