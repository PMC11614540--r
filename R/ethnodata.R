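#' Read the quote-level locomotor database
#'
#' Parses and validates a tabular text file (tab- or comma-delimited,
#' auto-detected from the header line) of coded ethnographic passages. Each
#' row is one quote describing one locomotor modality for one society.
#' Enumerations are parsed case-insensitively and returned in canonical
#' snake_case; empty cells map to absent (`NA`) or, for
#' `proficiency_evidence`, to `"none"`.
#'
#' Validation is strict and aggregates diagnostics before failing, so every
#' offending row is reported at once. Hard errors include: malformed
#' `society_id`, unknown `modality`, a `special_activity` that does not
#' match the modality (persistence hunting belongs to running, honey
#' climbing to climbing, underwater hunting to diving), further variables
#' assigned to a quote with no proficiency evidence (the coding scheme
#' assigns no further variables when engagement is not documented), and a
#' functional domain coded where it is not applicable (see
#' [domain_applicable()]).
#'
#' @param path path to the quotes table. Required columns:
#'   `society_id, document_id, page, modality, proficiency_evidence,
#'   functional_domains, special_activity, gender_evidence, excluded,
#'   exclusion_reason, note`. `functional_domains` is a `;`-separated set.
#' @return a `data.frame` of validated quote records, one row per quote,
#'   with `excluded` as logical and set-valued columns kept as canonical
#'   `;`-separated strings.
#' @seealso [write_quotes()], [eligible_societies()], [aggregate_codes()]
#' @export
read_quotes <- function(path) {
  df <- read_table_checked(path, QUOTE_COLUMNS)
  n <- nrow(df)
  problems <- character(0)
  note_bad <- function(i, msg) {
    problems <<- c(problems, sprintf("row %d: %s", i, msg))
  }

  df$society_id <- trimws(df$society_id)
  df$document_id <- trimws(df$document_id)
  df$modality <- canon_enum(df$modality)
  df$proficiency_evidence <- canon_enum(df$proficiency_evidence)
  df$special_activity <- canon_enum(df$special_activity)
  df$gender_evidence <- canon_enum(df$gender_evidence)
  df$exclusion_reason <- canon_enum(df$exclusion_reason)
  excl_raw <- canon_enum(df$excluded)

  df$proficiency_evidence[!nzchar(df$proficiency_evidence)] <- "none"
  df$special_activity[!nzchar(df$special_activity)] <- NA_character_
  df$gender_evidence[!nzchar(df$gender_evidence)] <- NA_character_
  df$exclusion_reason[!nzchar(df$exclusion_reason)] <- NA_character_

  excluded <- rep(NA, n)
  excluded[excl_raw %in% c("true", "1", "yes")] <- TRUE
  excluded[excl_raw %in% c("false", "0", "no", "")] <- FALSE
  df$excluded <- excluded

  domains_list <- vector("list", n)
  for (i in seq_len(n)) {
    if (!grepl("^[A-Za-z0-9_.-]+$", df$society_id[i])) {
      note_bad(i, paste0("unknown society_id format: '", df$society_id[i], "'"))
    }
    if (!df$modality[i] %in% MODALITIES) {
      note_bad(i, paste0("unknown modality: '", df$modality[i], "'"))
    }
    if (!df$proficiency_evidence[i] %in% QUOTE_PROFICIENCY) {
      note_bad(i, paste0("unknown proficiency_evidence: '",
                         df$proficiency_evidence[i], "'"))
    }
    doms <- canon_enum(split_set(df$functional_domains[i]))
    bad <- setdiff(doms, FUNCTIONAL_DOMAINS)
    if (length(bad)) {
      note_bad(i, paste0("unknown functional domain(s): ",
                         paste(bad, collapse = ", ")))
      doms <- intersect(doms, FUNCTIONAL_DOMAINS)
    }
    domains_list[[i]] <- doms
    if (is.na(df$excluded[i])) {
      note_bad(i, paste0("unparseable excluded flag: '", excl_raw[i], "'"))
    }
    sa <- df$special_activity[i]
    if (!is.na(sa)) {
      if (!sa %in% names(SPECIAL_ACTIVITY_MODALITY)) {
        note_bad(i, paste0("unknown special_activity: '", sa, "'"))
      } else if (df$modality[i] %in% MODALITIES &&
                 SPECIAL_ACTIVITY_MODALITY[[sa]] != df$modality[i]) {
        note_bad(i, paste0("special_activity '", sa,
                           "' is not legal for modality '", df$modality[i], "'"))
      }
    }
    ge <- df$gender_evidence[i]
    if (!is.na(ge) && !ge %in% GENDER_EVIDENCE) {
      note_bad(i, paste0("unknown gender_evidence: '", ge, "'"))
    }
    er <- df$exclusion_reason[i]
    if (!is.na(er) && !er %in% EXCLUSION_REASONS) {
      note_bad(i, paste0("unknown exclusion_reason: '", er, "'"))
    }
    if (isTRUE(df$excluded[i] == FALSE) && !is.na(er)) {
      note_bad(i, "exclusion_reason given but excluded is false")
    }
    if (df$proficiency_evidence[i] == "none") {
      if (length(doms) || !is.na(ge) || !is.na(sa)) {
        note_bad(i, paste0("proficiency_evidence is 'none' but further ",
                           "variables are assigned"))
      }
    }
    if (df$modality[i] %in% MODALITIES && length(doms)) {
      masked <- doms[!domain_applicable(doms, df$modality[i])]
      if (length(masked)) {
        note_bad(i, paste0("domain(s) not applicable to ", df$modality[i],
                           ": ", paste(masked, collapse = ", ")))
      }
    }
  }
  fail_rows(problems, paste0("invalid quote records in ", path))

  df$functional_domains <- vapply(
    domains_list, join_set, character(1), order = FUNCTIONAL_DOMAINS)
  rownames(df) <- NULL
  df
}

#' Write quote records in canonical form
#'
#' Serializes records produced by [read_quotes()] (or the synthetic
#' generator) as a UTF-8 tab-delimited table. Reading the file back yields
#' field-equivalent records, and identical inputs give byte-identical files.
#'
#' @param quotes data.frame of quote records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quotes <- function(quotes, path) {
  out <- quotes[QUOTE_COLUMNS]
  out$excluded <- ifelse(out$excluded, "true", "false")
  write_tsv(out, path)
}

#' Read the society covariate table
#'
#' Parses and validates societies with their subsistence-dependence
#' percentages and ecological covariates, and derives the six-way biome
#' simplification (`biome6`) from the WWF Major Habitat Type name via
#' [biome_simplify()].
#'
#' @param path path to the societies table. Required columns:
#'   `society_id, name, dependence_gathering, dependence_hunting,
#'   dependence_fishing, mht_category, mean_annual_temp_C,
#'   coast_distance_km`. Mean annual temperature may be negative; coast
#'   distance must be non-negative; each dependence percentage must lie in
#'   \[0, 100\] and the three must sum to at most 100.
#' @param biome_map optional named map from MHT names to the six biomes, as
#'   returned by [read_biome_map()]; defaults to the map shipped with the
#'   package.
#' @return a `data.frame` with numeric covariates and a `biome6` column.
#' @export
read_societies <- function(path, biome_map = NULL) {
  df <- read_table_checked(path, SOCIETY_COLUMNS)
  n <- nrow(df)
  problems <- character(0)
  note_bad <- function(i, msg) {
    problems <<- c(problems, sprintf("row %d: %s", i, msg))
  }

  df$society_id <- trimws(df$society_id)
  num_cols <- c("dependence_gathering", "dependence_hunting",
                "dependence_fishing", "mean_annual_temp_C",
                "coast_distance_km")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & nzchar(trimws(df[[cc]])))
    for (i in bad) note_bad(i, paste0("non-numeric ", cc, ": '", df[[cc]][i], "'"))
    df[[cc]] <- v
  }
  for (i in seq_len(n)) {
    if (!grepl("^[A-Za-z0-9_.-]+$", df$society_id[i])) {
      note_bad(i, paste0("unknown society_id format: '", df$society_id[i], "'"))
    }
    dep <- c(df$dependence_gathering[i], df$dependence_hunting[i],
             df$dependence_fishing[i])
    if (anyNA(dep)) {
      note_bad(i, "missing dependence percentage")
    } else {
      if (any(dep < 0 | dep > 100)) {
        note_bad(i, "dependence percentage outside [0, 100]")
      } else if (sum(dep) > 100) {
        note_bad(i, sprintf("dependence percentages sum to %.1f > 100", sum(dep)))
      }
    }
    if (!is.na(df$coast_distance_km[i]) && df$coast_distance_km[i] < 0) {
      note_bad(i, "negative coast_distance_km")
    }
  }
  if (anyDuplicated(df$society_id)) {
    problems <- c(problems, paste0(
      "duplicated society_id: ",
      paste(unique(df$society_id[duplicated(df$society_id)]), collapse = ", ")))
  }
  fail_rows(problems, paste0("invalid society records in ", path))

  df$biome6 <- biome_simplify(df$mht_category, biome_map)
  rownames(df) <- NULL
  df
}

#' Write the society table in canonical form
#'
#' @param societies data.frame from [read_societies()] (the derived
#'   `biome6` column, if present, is included).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_societies <- function(societies, path) {
  cols <- c(SOCIETY_COLUMNS, intersect("biome6", names(societies)))
  write_tsv(societies[cols], path)
}

#' Apply the sample-eligibility gate
#'
#' A society enters the analysis sample when (i) its cumulative dependence
#' on gathering, hunting and fishing strictly exceeds
#' `dependence_threshold` percent, and (ii) at least `min_quotes`
#' non-excluded quotes relevant to locomotion were identified for it.
#' Excluded quotes (myths/legends, non-traditional lifeways, ambiguous
#' terms) do not count towards the quote threshold. The gate is idempotent
#' and independent of row order.
#'
#' @param societies data.frame from [read_societies()].
#' @param quotes data.frame from [read_quotes()].
#' @param dependence_threshold strict lower bound on the dependence sum,
#'   in percent (default 56).
#' @param min_quotes minimum number of non-excluded quotes (default 2).
#' @return a list with `eligible` (the retained society rows, input order)
#'   and `excluded` (a data.frame of `society_id`, `reason` in
#'   `{low_dependence, insufficient_quotes}`).
#' @export
#' @examples
#' soc <- data.frame(society_id = "s1", name = "toy",
#'                   dependence_gathering = 40, dependence_hunting = 20,
#'                   dependence_fishing = 5, mht_category = "Tundra",
#'                   mean_annual_temp_C = -10, coast_distance_km = 3,
#'                   biome6 = "Tundra")
#' q <- data.frame(society_id = "s1", modality = "running",
#'                 proficiency_evidence = "basic", excluded = FALSE)
#' eligible_societies(soc, q)$excluded$reason  # insufficient_quotes
eligible_societies <- function(societies, quotes,
                               dependence_threshold = 56, min_quotes = 2) {
  stopifnot(dependence_threshold > 0, min_quotes >= 0)
  dep_sum <- societies$dependence_gathering + societies$dependence_hunting +
    societies$dependence_fishing
  relevant <- quotes[!quotes$excluded, , drop = FALSE]
  counts <- table(factor(relevant$society_id, levels = societies$society_id))
  n_quotes <- as.integer(counts[societies$society_id])

  dep_ok <- dep_sum > dependence_threshold
  quo_ok <- n_quotes >= min_quotes
  keep <- dep_ok & quo_ok

  reason <- ifelse(!dep_ok, "low_dependence", "insufficient_quotes")
  excluded <- data.frame(
    society_id = societies$society_id[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  list(
    eligible = societies[keep, , drop = FALSE],
    excluded = excluded
  )
}
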