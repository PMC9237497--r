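trait_csv_cols <- c("variety", "generation", "treatment", "line",
                    "replicate", "trait", "value")

#' Read a replicate-level trait table from CSV
#'
#' Strict reader for the long-format interchange schema (columns
#' `variety, generation, treatment, line, replicate, trait, value`).
#' Validation errors cite the offending file line (header = line 1):
#' missing columns, missing values (distinguished from malformed
#' numbers), non-integer replicate indices, and duplicated
#' (variety, generation, treatment, line, replicate, trait) keys.
#'
#' @param path CSV file path (UTF-8, "." decimal separator).
#' @return A validated trait-table tibble.
#' @export
read_trait_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  miss <- setdiff(trait_csv_cols, names(raw))
  if (length(miss) > 0) {
    abort(paste0("missing column(s): ", paste(miss, collapse = ", "), "."))
  }
  line_no <- seq_len(nrow(raw)) + 1L  # header occupies line 1
  fail <- function(what, rows) {
    abort(paste0(what, " at line(s) ",
                 paste(head(line_no[rows], 5), collapse = ", "),
                 if (sum(rows) > 5) " ..." else "", "."))
  }
  missing_val <- raw$value %in% c("", "NA", "NaN")
  if (any(missing_val)) fail("missing value", missing_val)
  value <- suppressWarnings(as.numeric(raw$value))
  if (any(is.na(value))) fail("malformed (non-numeric) value", is.na(value))
  if (any(!is.finite(value))) fail("non-finite value", !is.finite(value))
  replicate <- suppressWarnings(as.integer(raw$replicate))
  if (any(is.na(replicate))) fail("malformed replicate index", is.na(replicate))
  key <- do.call(paste, c(raw[, setdiff(trait_csv_cols, "value")], sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) fail("duplicate (variety, generation, treatment, line, replicate, trait) key", dup)
  raw$replicate <- replicate
  raw$value <- value
  select(raw, all_of(trait_csv_cols))
}

#' Write a trait table to CSV
#'
#' @param table A trait table.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trait_csv <- function(table, path) {
  table <- as_tibble(table)
  miss <- setdiff(trait_csv_cols, names(table))
  if (length(miss) > 0) {
    abort(paste0("missing column(s): ", paste(miss, collapse = ", "), "."))
  }
  readr::write_csv(table[, trait_csv_cols], path, progress = FALSE)
  invisible(path)
}

format_mean_cell <- function(mean, letters, se) {
  letters <- ifelse(is.na(letters) | letters == "", "a", letters)
  sprintf("%.2f^%s ± %.2f", round_half_up(mean, 2), letters,
          round_half_up(se, 2))
}

#' Render a population summary as a report-style text table
#'
#' Formats [population_summary()] rows the way the trial's printed tables
#' read: per trait, a MEAN row of `mean^letters ± SE` cells (2
#' decimals, half rounded away from zero) followed by GCV%, h2% and GA
#' rows, one column per treatment.
#'
#' @param rows Output of [population_summary()].
#' @return Character vector of text lines (one per table row), invisibly
#'   printed with `cat()` when interactive use wants it.
#' @export
render_summary <- function(rows) {
  rows <- as_tibble(rows)
  req <- c("treatment", "trait", "mean", "se_mean", "letters",
           "gcv_pct", "h2_pct", "ga_pct")
  miss <- setdiff(req, names(rows))
  if (length(miss) > 0) {
    abort(paste0("missing column(s): ", paste(miss, collapse = ", "), "."))
  }
  treatments <- unique(rows$treatment)
  traits <- unique(rows$trait)
  fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))
  lines_out <- character(0)
  pad <- function(cells) paste(format(cells, width = max(nchar(cells))),
                               collapse = "  ")
  header <- pad(c("", "", treatments))
  lines_out <- c(lines_out, header)
  for (t in traits) {
    sub <- rows[rows$trait == t, ]
    sub <- sub[match(treatments, sub$treatment), ]
    lines_out <- c(
      lines_out,
      pad(c(t, "MEAN", format_mean_cell(sub$mean, sub$letters, sub$se_mean))),
      pad(c("", "GCV%", fmt2(sub$gcv_pct))),
      pad(c("", "h2%", fmt2(sub$h2_pct))),
      pad(c("", "GA", fmt2(sub$ga_pct)))
    )
  }
  lines_out
}
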