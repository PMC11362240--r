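# ---------------------------------------------------------------------------
# Per-participant response-frequency tables
#
# A freq_table is a tibble with a `participant` column and one integer count
# column per tree x category cell, named "<tree>:<category>".  The study
# design (items presented per tree) travels as the "design" attribute, a
# tibble with columns `tree` and `items`.
# ---------------------------------------------------------------------------

#' Build a response-frequency table
#'
#' @param counts A data frame or matrix of non-negative integer counts, one
#'   row per participant, columns named `"<tree>:<category>"`.
#' @param design A data frame with columns `tree` and `items`: the number of
#'   items presented per tree to each participant.
#' @param participants Optional participant IDs (default `p1`, `p2`, ...).
#' @return A `freq_table` tibble.
#' @export
freq_table <- function(counts, design, participants = NULL) {
  counts <- as.data.frame(counts)
  if ("participant" %in% names(counts)) {
    participants <- counts$participant
    counts$participant <- NULL
  }
  if (is.null(participants)) participants <- paste0("p", seq_len(nrow(counts)))
  design <- as_tibble(design)
  stopifnot(all(c("tree", "items") %in% names(design)))
  cols <- names(counts)
  parsed <- strsplit(cols, ":", fixed = TRUE)
  if (any(lengths(parsed) != 2L)) {
    abort("count columns must be named '<tree>:<category>'",
          class = "ordtree_value_error")
  }
  trees <- vapply(parsed, `[[`, character(1), 1L)
  if (!setequal(unique(trees), design$tree)) {
    abort("count columns and design trees do not match",
          class = "ordtree_value_error")
  }
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m))) {
    abort("counts must be non-negative integers", class = "ordtree_value_error")
  }
  for (tr in design$tree) {
    tot <- rowSums(m[, trees == tr, drop = FALSE])
    want <- design$items[design$tree == tr]
    if (any(tot != want)) {
      abort(paste0("counts in tree '", tr, "' do not sum to the design's ",
                   want, " items for every participant"),
            class = "ordtree_value_error")
    }
  }
  out <- tibble(participant = as.character(participants))
  out <- dplyr::bind_cols(out, as_tibble(as.data.frame(m)))
  attr(out, "design") <- design
  class(out) <- c("freq_table", class(out))
  out
}

#' Design metadata of a frequency table
#' @param data A `freq_table`.
#' @return A tibble with columns `tree` and `items`.
#' @export
freq_design <- function(data) {
  d <- attr(data, "design")
  if (is.null(d)) abort("no design attribute on this table")
  d
}

# Internal: split a freq_table into the per-tree count matrices matching a
# model's tree and category order.
split_counts <- function(data, model) {
  cols <- setdiff(names(data), "participant")
  mat <- as.matrix(data[, cols, drop = FALSE])
  lapply(model$trees, function(tr) {
    want <- paste0(tr$name, ":", tr$categories)
    miss <- setdiff(want, cols)
    if (length(miss)) {
      abort(paste0("frequency table lacks column(s): ",
                   paste(miss, collapse = ", ")),
            class = "ordtree_value_error")
    }
    m <- mat[, want, drop = FALSE]
    colnames(m) <- tr$categories
    m
  })
}

#' Write / read a frequency table as delimited text
#'
#' The on-disk format is tab-separated with a `participant` column and one
#' column per tree x category cell; the design is stored in `#` header
#' comments so the file round-trips.
#'
#' @param data A `freq_table`.
#' @param path File path.
#' @return `read_freq_table()` returns a `freq_table`;
#'   `write_freq_table()` returns the path invisibly.
#' @export
write_freq_table <- function(data, path) {
  design <- freq_design(data)
  hdr <- paste0("# design ", design$tree, " ", design$items)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(data), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_freq_table
#' @export
read_freq_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  dh <- grep("^# design ", lines, value = TRUE)
  if (!length(dh)) abort("missing '# design' header lines",
                         class = "ordtree_format_error")
  toks <- strsplit(sub("^# design ", "", dh), " ")
  design <- tibble(tree = vapply(toks, `[[`, character(1), 1L),
                   items = as.integer(vapply(toks, `[[`, character(1), 2L)))
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  freq_table(df, design)
}
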