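#' Load an instrument definition (item bank) from a YAML config
#'
#' The item bank defines the instrument: the multiple-choice knowledge
#' items with their keyed correct answers, the goal/concern items rated on
#' a 0-10 importance scale, the five-item brief-version subset, and the
#' goals used as covariates of the preference model. The packaged default
#' (`default_item_bank()`) ships the 10 retained knowledge items and the 8
#' retained goals of the field-tested CRC-DQI.
#'
#' @param path path to a YAML item-bank file (see
#'   `system.file("extdata", "crc_dqi_bank.yaml", package = "crcdqi")` for
#'   the documented schema).
#' @return an object of class `crcdqi_bank`: a list with elements
#'   `knowledge_items` (tibble: `item_id`, `prompt`, `options` list-column,
#'   `correct_option`), `goal_items` (tibble: `goal_id`, `prompt`,
#'   `scale_min`, `scale_max`), `brief_subset` (character, length 5) and
#'   `model_goals` (character).
#' @export
load_item_bank <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("item-bank file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  new_item_bank(cfg)
}

#' @rdname load_item_bank
#' @export
default_item_bank <- function() {
  load_item_bank(system.file("extdata", "crc_dqi_bank.yaml", package = "crcdqi"))
}

# Construct and validate a bank from a parsed config list.
new_item_bank <- function(cfg) {
  for (field in c("knowledge_items", "goal_items", "brief_subset")) {
    if (is.null(cfg[[field]])) abort_config(sprintf("item-bank config missing field '%s'", field))
  }
  scale <- cfg$goal_scale %||% list(min = 0, max = 10)

  ki <- tibble::tibble(
    item_id = vapply(cfg$knowledge_items, function(x) as.character(x$item_id), ""),
    prompt = vapply(cfg$knowledge_items, function(x) as.character(x$prompt %||% ""), ""),
    options = lapply(cfg$knowledge_items, function(x) as.character(unlist(x$options))),
    correct_option = vapply(cfg$knowledge_items, function(x) as.character(x$correct_option), "")
  )
  gi <- tibble::tibble(
    goal_id = vapply(cfg$goal_items, function(x) as.character(x$goal_id), ""),
    prompt = vapply(cfg$goal_items, function(x) as.character(x$prompt %||% ""), ""),
    scale_min = as.integer(scale$min),
    scale_max = as.integer(scale$max)
  )

  if (anyDuplicated(ki$item_id)) {
    abort_config(sprintf("duplicate item_id in knowledge_items: %s",
                         paste(unique(ki$item_id[duplicated(ki$item_id)]), collapse = ", ")))
  }
  if (anyDuplicated(gi$goal_id)) {
    abort_config(sprintf("duplicate goal_id in goal_items: %s",
                         paste(unique(gi$goal_id[duplicated(gi$goal_id)]), collapse = ", ")))
  }
  bad_key <- !mapply(function(opts, key) key %in% opts, ki$options, ki$correct_option)
  if (any(bad_key)) {
    abort_config(sprintf("correct_option not among options for item(s): %s",
                         paste(ki$item_id[bad_key], collapse = ", ")))
  }
  brief <- as.character(unlist(cfg$brief_subset))
  if (length(brief) != 5L) {
    abort_config(sprintf("brief_subset must have exactly 5 items, got %d", length(brief)))
  }
  if (!all(brief %in% ki$item_id)) {
    abort_config(sprintf("brief_subset contains unknown item id(s): %s",
                         paste(setdiff(brief, ki$item_id), collapse = ", ")))
  }
  model_goals <- as.character(unlist(cfg$model_goals %||% gi$goal_id))
  if (!all(model_goals %in% gi$goal_id)) {
    abort_config(sprintf("model_goals contains unknown goal id(s): %s",
                         paste(setdiff(model_goals, gi$goal_id), collapse = ", ")))
  }

  structure(
    list(knowledge_items = ki, goal_items = gi,
         brief_subset = brief, model_goals = model_goals),
    class = "crcdqi_bank"
  )
}

#' Write an item bank back to a YAML config
#'
#' Round-trip companion of [load_item_bank()]: writing a bank and reloading
#' it yields an identical bank.
#'
#' @param bank a `crcdqi_bank`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "crcdqi_bank"))
  cfg <- list(
    knowledge_items = lapply(seq_len(nrow(bank$knowledge_items)), function(i) {
      row <- bank$knowledge_items[i, ]
      list(item_id = row$item_id, prompt = row$prompt,
           options = row$options[[1]], correct_option = row$correct_option)
    }),
    goal_items = lapply(seq_len(nrow(bank$goal_items)), function(i) {
      row <- bank$goal_items[i, ]
      list(goal_id = row$goal_id, prompt = row$prompt)
    }),
    brief_subset = bank$brief_subset,
    model_goals = bank$model_goals,
    goal_scale = list(min = bank$goal_items$scale_min[1],
                      max = bank$goal_items$scale_max[1])
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @export
print.crcdqi_bank <- function(x, ...) {
  cat(sprintf("<crcdqi_bank> %d knowledge items, %d goals\n",
              nrow(x$knowledge_items), nrow(x$goal_items)))
  cat(sprintf("  brief subset: %s\n", paste(x$brief_subset, collapse = ", ")))
  cat(sprintf("  model goals:  %s\n", paste(x$model_goals, collapse = ", ")))
  invisible(x)
}

knowledge_cols <- function(bank) bank$knowledge_items$item_id
goal_cols <- function(bank) bank$goal_items$goal_id

#' Validate respondent records against an item bank
#'
#' Checks each record for out-of-range goal ratings, knowledge responses
#' that are not among the item's response options, and out-of-range field
#' values. Findings are returned, never raised: validation is a report, not
#' a gate.
#'
#' @param cohort a respondent data frame (see [read_responses()] for the
#'   column dictionary). A single record is a one-row data frame.
#' @param bank a `crcdqi_bank`.
#' @return tibble of findings with columns `respondent_id`, `column`,
#'   `value`, `message`; zero rows when every record is clean.
#' @export
validate_responses <- function(cohort, bank) {
  stopifnot(inherits(bank, "crcdqi_bank"))
  cohort <- as_cohort(cohort, bank, check = FALSE)
  findings <- list()
  add <- function(id, column, value, message) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(
      respondent_id = as.character(id), column = column,
      value = as.character(value), message = message
    )
  }
  smin <- bank$goal_items$scale_min[1]
  smax <- bank$goal_items$scale_max[1]
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$respondent_id[i]
    for (k in seq_len(nrow(bank$knowledge_items))) {
      iid <- bank$knowledge_items$item_id[k]
      resp <- cohort[[iid]][i]
      if (!is.na(resp) && !(resp %in% bank$knowledge_items$options[[k]])) {
        add(id, iid, resp, "response not among the item's options")
      }
    }
    for (g in goal_cols(bank)) {
      val <- cohort[[g]][i]
      if (!is.na(val) && (val < smin || val > smax || val != floor(val))) {
        add(id, g, val, sprintf("goal rating outside %d-%d integer scale", smin, smax))
      }
    }
    tt <- parse_top_three(cohort$top_three[i])
    if (length(tt) > 3L) {
      add(id, "top_three", cohort$top_three[i], "more than three goals selected")
    }
    unknown <- setdiff(tt, goal_cols(bank))
    if (length(unknown)) {
      add(id, "top_three", paste(unknown, collapse = ";"), "unknown goal id in top_three")
    }
  }
  if (!length(findings)) {
    return(tibble::tibble(respondent_id = character(), column = character(),
                          value = character(), message = character()))
  }
  dplyr::bind_rows(findings)
}
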