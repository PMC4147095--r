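# Delimited-text I/O. Dialect: comma-separated, UTF-8, header row
# required, empty field = missing. The round trip write -> read is
# lossless for every field including missingness.

#' Read a respondent response file
#'
#' @param path CSV file in the [response_schema()] layout.
#' @param bank a `crcdqi_bank` used to type the item/goal columns.
#' @return respondent tibble. Unknown columns are kept with a warning;
#'   malformed values (non-integer goal ratings, non-numeric ages) raise
#'   an error naming the row and column.
#' @export
read_responses <- function(path, bank = default_item_bank()) {
  if (!file.exists(path)) abort_data(sprintf("response file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = "", progress = FALSE)
  needed <- c(core_cols, knowledge_cols(bank), goal_cols(bank))
  extra <- setdiff(names(raw), needed)
  if (length(extra)) {
    warning(sprintf("unknown column(s) kept as-is: %s", paste(extra, collapse = ", ")))
  }
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort_data(sprintf("%s: missing required column(s): %s", path,
                       paste(missing_cols, collapse = ", ")))
  }
  parse_num <- function(col, as_int = FALSE) {
    vals <- raw[[col]]
    out <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(out))
    if (length(bad)) {
      abort_data(sprintf("%s: malformed value '%s' in row %d, column %s",
                         path, vals[bad[1]], bad[1], col))
    }
    if (as_int) {
      frac <- which(!is.na(out) & out != floor(out))
      if (length(frac)) {
        abort_data(sprintf("%s: non-integer value '%s' in row %d, column %s",
                           path, vals[frac[1]], frac[1], col))
      }
      as.integer(out)
    } else out
  }
  raw$age <- parse_num("age")
  raw$involvement_level <- parse_num("involvement_level", as_int = TRUE)
  for (g in goal_cols(bank)) raw[[g]] <- parse_num(g, as_int = TRUE)
  for (col in c("timepoint", "arm", "mode", "screening_history", "decision_maker")) {
    allowed <- switch(col, timepoint = timepoint_levels, arm = arm_levels,
                      mode = mode_levels, screening_history = screening_levels,
                      decision_maker = decision_maker_levels)
    bad <- which(!is.na(raw[[col]]) & !(raw[[col]] %in% allowed))
    if (length(bad)) {
      abort_data(sprintf("%s: invalid value '%s' in row %d, column %s (allowed: %s)",
                         path, raw[[col]][bad[1]], bad[1], col,
                         paste(allowed, collapse = ", ")))
    }
  }
  as_cohort(raw, bank)
}

#' Write respondents to a response file
#'
#' @param cohort respondent tibble.
#' @param path output CSV path; missing values become empty fields.
#' @return `path`, invisibly.
#' @export
write_responses <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Render an analysis report
#'
#' Writes machine-readable tables at full precision (`format = "csv"`) or
#' a human-readable markdown summary with display rounding
#' (`format = "md"`). Every summary line carries the exact denominator it
#' was computed over.
#'
#' @param results named list of tibbles/lists produced by the analysis
#'   functions (e.g. `item_difficulty`, `knowledge_mean`, `concordance`,
#'   `dqi`, `reliability`, `feasibility`).
#' @param path output file path.
#' @param format `"csv"` (one file per table, suffixed by name) or `"md"`.
#' @return paths written, invisibly.
#' @export
write_report <- function(results, path, format = c("md", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    written <- character()
    stem <- sub("\\.csv$", "", path)
    for (nm in names(results)) {
      x <- results[[nm]]
      tab <- if (is.data.frame(x)) x else tibble::as_tibble(x[vapply(x, is.atomic, TRUE)])
      out <- sprintf("%s_%s.csv", stem, nm)
      readr::write_csv(tab, out, na = "")
      written <- c(written, out)
    }
    return(invisible(written))
  }
  lines <- c("# CRC-DQI analysis report", "")
  fmt_pct <- function(x, d = 1) sprintf(paste0("%.", d, "f%%"), round_half_up(x, d))
  for (nm in names(results)) {
    x <- results[[nm]]
    lines <- c(lines, sprintf("## %s", nm), "")
    if (inherits(x, "crcdqi_concordance")) {
      lines <- c(lines, sprintf("- matched: %d / %d = %s", x$n_match, x$n_eligible,
                                fmt_pct(x$concordance_pct)))
    } else if (inherits(x, "crcdqi_dqi")) {
      lines <- c(lines,
                 sprintf("- high decision quality: %d / %d = %s", x$n_high_quality,
                         x$n_total, fmt_pct(x$pct)),
                 sprintf("- informed threshold: %s (knowledge score at or above)",
                         fmt_pct(x$threshold_used, 0)))
    } else if (is.data.frame(x)) {
      lines <- c(lines, md_table(x), "")
    } else if (is.list(x)) {
      for (f in names(x)) {
        v <- x[[f]]
        if (is.numeric(v) && length(v) == 1) {
          shown <- if (grepl("pct|rate", f)) fmt_pct(v) else format(round_half_up(v, 3))
          lines <- c(lines, sprintf("- %s: %s", f, shown))
        } else if (is.data.frame(v)) {
          lines <- c(lines, sprintf("### %s", f), "", md_table(v), "")
        }
      }
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

md_table <- function(df, digits = 3) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- format(round_half_up(df[[j]], digits))
    if (is.list(df[[j]])) df[[j]] <- vapply(df[[j]], paste, "", collapse = "|")
  }
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
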