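# Respondent-record schema. A cohort is a plain tibble, one row per
# respondent per timepoint, with one column per knowledge item (option
# label or NA) and per goal (integer rating 0-10 or NA). Keeping records
# as flat rows makes the delimited-file round trip trivially lossless.

arm_levels <- c("decision_aid", "control", "none")
mode_levels <- c("online", "mail", "in_person")
timepoint_levels <- c("test", "retest")
screening_levels <- c("never", "colonoscopy", "other_test")
decision_maker_levels <- c("patient", "doctor", "shared")

core_cols <- c("respondent_id", "timepoint", "arm", "mode", "age",
               "sex", "education", "race", "screening_history",
               "top_three", "decision_maker", "involvement_level")

#' Column dictionary for respondent response files
#'
#' Describes the delimited-text schema used by [read_responses()] and
#' [write_responses()]: one row per respondent per timepoint, empty field
#' means missing.
#'
#' @param bank a `crcdqi_bank` supplying the item and goal columns.
#' @return tibble with columns `column`, `type`, `allowed`, `description`.
#' @export
response_schema <- function(bank = default_item_bank()) {
  dplyr::bind_rows(
    tibble::tibble(
      column = core_cols,
      type = c("character", "enum", "enum", "enum", "numeric",
               "character", "character", "character", "enum",
               "character", "enum", "integer"),
      allowed = c("", paste(timepoint_levels, collapse = "|"),
                  paste(arm_levels, collapse = "|"),
                  paste(mode_levels, collapse = "|"), "",
                  "", "", "", paste(screening_levels, collapse = "|"),
                  "semicolon-separated goal ids, at most 3",
                  paste(decision_maker_levels, collapse = "|"), "1-4"),
      description = c("unique respondent identifier",
                      "administration occasion",
                      "randomized study arm (none for non-randomized samples)",
                      "mode of administration",
                      "age in years",
                      "self-reported sex", "education level", "race",
                      "screening history (empty if not asked, e.g. under 50)",
                      "top-three goals most important to the decision",
                      "who made the screening decision",
                      "self-rated involvement (1 low - 4 high)")
    ),
    tibble::tibble(
      column = knowledge_cols(bank), type = "character",
      allowed = vapply(bank$knowledge_items$options, paste, "", collapse = "|"),
      description = paste("knowledge item response label:",
                          substr(bank$knowledge_items$prompt, 1, 60))
    ),
    tibble::tibble(
      column = goal_cols(bank), type = "integer",
      allowed = sprintf("%d-%d", bank$goal_items$scale_min, bank$goal_items$scale_max),
      description = paste("importance rating:", substr(bank$goal_items$prompt, 1, 60))
    )
  )
}

parse_top_three <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  strsplit(x, ";", fixed = TRUE)[[1]]
}

# Coerce a data frame to the cohort schema, checking required columns.
as_cohort <- function(cohort, bank, check = TRUE) {
  cohort <- tibble::as_tibble(cohort)
  needed <- c(core_cols, knowledge_cols(bank), goal_cols(bank))
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    if (check) {
      abort_data(sprintf("cohort is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
    }
    for (col in missing_cols) {
      cohort[[col]] <- if (col %in% goal_cols(bank)) NA_integer_ else NA_character_
    }
  }
  cohort$respondent_id <- as.character(cohort$respondent_id)
  for (g in goal_cols(bank)) cohort[[g]] <- as.integer(cohort[[g]])
  for (k in knowledge_cols(bank)) cohort[[k]] <- as.character(cohort[[k]])
  cohort$age <- as.numeric(cohort$age)
  cohort
}
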