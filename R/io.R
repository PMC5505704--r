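#' Histogram table container
#'
#' Uniform, contiguous histogram in the layout of the per-figure source
#' data tables (bin left edge plus count), with quantity, condition and
#' bandwidth metadata.
#'
#' @param bin_left Left bin edges (uniform spacing).
#' @param count Non-negative integer counts, same length.
#' @param quantity Measured quantity (e.g. `"force_pN"`,
#'   `"contour_length_nm"`).
#' @param condition Condition label.
#' @param bandwidth Bin width or KDE bandwidth used.
#' @return An object of class `histogram_table` (a data frame with
#'   metadata attributes).
#' @export
histogram_table <- function(bin_left, count, quantity = "",
                            condition = "", bandwidth = NA_real_) {
  stopifnot(length(bin_left) == length(count), all(count >= 0))
  if (length(bin_left) > 2) {
    w <- diff(bin_left)
    stopifnot(max(abs(w - w[1])) < 1e-9 * max(abs(w[1]), 1))
  }
  structure(data.frame(bin_left = bin_left, count = as.integer(count)),
            quantity = quantity, condition = condition,
            bandwidth = bandwidth,
            class = c("histogram_table", "data.frame"))
}

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 10)
  gsub(" ", "", out)
}

write_header <- function(con, keys) {
  for (k in names(keys))
    if (!is.null(keys[[k]]) && !is.na(keys[[k]]))
      writeLines(sprintf("#%s=%s", k, format(keys[[k]])), con)
}

read_header <- function(lines) {
  hl <- grep("^#", lines, value = TRUE)
  kv <- sub("^#", "", hl)
  kv <- kv[grepl("=", kv)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

#' Write a force curve as tab-separated text
#'
#' Format: `#key=value` header lines (at minimum `speed` in nm/s and
#' `spring_constant` in pN/nm) followed by a tab-separated numeric body
#' of piezo distance (nm) and force (pN), plus a time column (s) when
#' available. Output bytes are deterministic for identical input.
#'
#' @param curve A [force_curve()].
#' @param path Output file path.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  md <- curve$metadata
  con <- file(path, open = "wt")
  on.exit(close(con))
  write_header(con, list(speed = md$retraction_speed,
                         spring_constant = md$spring_constant,
                         sampling_rate = md$sampling_rate,
                         noise_sd = md$noise_sd,
                         condition = md$condition,
                         characteristic = md$characteristic,
                         columns = if (is.null(curve$time))
                           "distance_nm\tforce_pN" else
                             "distance_nm\tforce_pN\ttime_s"))
  body <- if (is.null(curve$time))
    paste(fmt_num(curve$distance), fmt_num(curve$force), sep = "\t")
  else
    paste(fmt_num(curve$distance), fmt_num(curve$force),
          fmt_num(curve$time), sep = "\t")
  writeLines(body, con)
  invisible(NULL)
}

#' Read a force curve from tab-separated text
#'
#' Counterpart of [write_curve()]. Mandatory header keys are `speed` and
#' `spring_constant`; a third numeric column, when present, is read as
#' sample time in seconds. Malformed numeric rows and non-monotone
#' distance are reported as format errors with line numbers.
#'
#' @param path File path.
#' @return A [force_curve()].
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- read_header(lines)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("empty curve body in ", path)
  if (is.null(hdr$speed) || is.null(hdr$spring_constant))
    stop("missing mandatory header key(s) (speed, spring_constant) in ",
         path)
  parts <- strsplit(body, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 2 | ncol > 3))
    stop("malformed row(s) in ", path, " at body line(s) ",
         paste(head(which(ncol < 2 | ncol > 3), 5), collapse = ", "))
  vals <- suppressWarnings(lapply(parts, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad))
    stop("non-numeric value(s) in ", path, " at body line(s) ",
         paste(head(bad, 5), collapse = ", "))
  m <- do.call(rbind, lapply(vals, function(v) c(v, NA)[1:3]))
  distance <- m[, 1]
  if (any(diff(distance) <= 0))
    stop("non-monotone distance column in ", path, " at body line ",
         which(diff(distance) <= 0)[1] + 1)
  md <- list(retraction_speed = as.numeric(hdr$speed),
             spring_constant = as.numeric(hdr$spring_constant),
             sampling_rate = if (!is.null(hdr$sampling_rate))
               as.numeric(hdr$sampling_rate) else NULL,
             noise_sd = if (!is.null(hdr$noise_sd))
               as.numeric(hdr$noise_sd) else NULL,
             condition = hdr$condition %||% NA_character_,
             characteristic = if (!is.null(hdr$characteristic))
               as.logical(hdr$characteristic) else NA)
  force_curve(distance, m[, 2],
              time = if (all(!is.na(m[, 3]))) m[, 3] else NULL,
              metadata = md)
}

#' Write / read a histogram table
#'
#' Tab-separated `bin_left` and `count` columns under `#key=value`
#' metadata (quantity, condition, bandwidth). Deterministic byte output.
#'
#' @param table A [histogram_table()].
#' @param path File path.
#' @export
write_histogram <- function(table, path) {
  stopifnot(inherits(table, "histogram_table"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  write_header(con, list(quantity = attr(table, "quantity"),
                         condition = attr(table, "condition"),
                         bandwidth = attr(table, "bandwidth"),
                         columns = "bin_left\tcount"))
  writeLines(paste(fmt_num(table$bin_left), table$count, sep = "\t"), con)
  invisible(NULL)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- read_header(lines)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("empty histogram body in ", path)
  parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  histogram_table(as.numeric(parts[, 1]), as.integer(parts[, 2]),
                  quantity = hdr$quantity %||% "",
                  condition = hdr$condition %||% "",
                  bandwidth = if (!is.null(hdr$bandwidth))
                    as.numeric(hdr$bandwidth) else NA_real_)
}

#' Write a heatmap grid as a dense delimited matrix plus axis sidecar
#'
#' The counts matrix is written as tab-separated rows (one row per
#' distance bin); bin edges for both axes go to a sidecar file at
#' `<path>.axes.tsv`.
#'
#' @param grid A [build_heatmap()] result.
#' @param path Output path for the dense grid.
#' @export
write_heatmap <- function(grid, path) {
  stopifnot(inherits(grid, "heatmap_grid"))
  con <- file(path, open = "wt")
  write_header(con, list(rows = "distance_bins", cols = "force_bins",
                         n_in_range = grid$n_in_range))
  writeLines(apply(grid$counts, 1, paste, collapse = "\t"), con)
  close(con)
  axes <- file(paste0(path, ".axes.tsv"), open = "wt")
  writeLines("axis\tbreak", axes)
  writeLines(paste("distance_nm", fmt_num(grid$distance_breaks), sep = "\t"),
             axes)
  writeLines(paste("force_pN", fmt_num(grid$force_breaks), sep = "\t"),
             axes)
  close(axes)
  invisible(NULL)
}

#' Write / read a dataset manifest
#'
#' Key-value text grouping per-curve files: a `#reference_condition=`
#' header and tab-separated `path`, `condition`, `cantilever` columns.
#' Paths must be unique and conditions recognized.
#'
#' @param entries Data frame with columns `path`, `condition`,
#'   `cantilever`.
#' @param reference_condition Condition anchoring Fn3 normalization.
#' @param path Manifest file path.
#' @export
write_manifest <- function(entries, reference_condition, path) {
  stopifnot(is.data.frame(entries),
            all(c("path", "condition", "cantilever") %in% names(entries)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  write_header(con, list(reference_condition = reference_condition,
                         columns = "path\tcondition\tcantilever"))
  writeLines(paste(entries$path, entries$condition, entries$cantilever,
                   sep = "\t"), con)
  invisible(NULL)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- read_header(lines)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("empty manifest: ", path)
  parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  entries <- data.frame(path = parts[, 1], condition = parts[, 2],
                        cantilever = parts[, 3],
                        stringsAsFactors = FALSE)
  if (anyDuplicated(entries$path))
    stop("duplicate curve path(s) in manifest: ", path)
  bad <- setdiff(unique(entries$condition), condition_labels)
  if (length(bad))
    stop("unrecognized condition(s) in manifest: ",
         paste(bad, collapse = ", "))
  list(entries = entries,
       reference_condition = hdr$reference_condition %||% NA_character_)
}
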