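#' Resolve society-level gender engagement from quote evidence
#'
#' Combines the gender-evidence values attached to the non-excluded quotes
#' of one society and modality into a single society-level code, using a
#' fixed precedence:
#'
#' 1. no evidence -> `insufficient_info`;
#' 2. an exclusivity code stands only while no other quote documents
#'    engagement by the other gender (a bias code or `both_no_bias`
#'    documents engagement by both genders);
#' 3. a contradicted exclusivity, or any one-sided bias, yields the
#'    corresponding bias code;
#' 4. engagement by both genders with no directional statement yields
#'    `both_no_bias`;
#' 5. evidence pointing in both directions (e.g. a female bias and a male
#'    bias) is treated as egalitarian engagement: `both_no_bias`, with a
#'    warning.
#'
#' @param evidence character vector of quote-level gender-evidence values
#'   (subset of `female_exclusive, male_exclusive, female_bias, male_bias,
#'   both_no_bias`); `NA`s are dropped.
#' @return a single gender code string.
#' @export
#' @examples
#' resolve_gender(character(0))                       # insufficient_info
#' resolve_gender("male_exclusive")                   # male_exclusive
#' resolve_gender(c("male_exclusive", "both_no_bias")) # male_bias
resolve_gender <- function(evidence) {
  ev <- evidence[!is.na(evidence)]
  if (!length(ev)) return("insufficient_info")
  bad <- setdiff(ev, GENDER_EVIDENCE)
  if (length(bad)) {
    stop("unknown gender evidence value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  female_dir <- any(ev %in% c("female_exclusive", "female_bias"))
  male_dir <- any(ev %in% c("male_exclusive", "male_bias"))
  if (female_dir && male_dir) {
    warning("conflicting gender-direction evidence; resolved to both_no_bias",
            call. = FALSE)
    return("both_no_bias")
  }
  if (any(ev == "female_exclusive")) {
    # male engagement is documented by both_no_bias and by female_bias
    # (a bias statement implies both genders engage)
    other <- any(ev %in% c("both_no_bias", "female_bias"))
    return(if (other) "female_bias" else "female_exclusive")
  }
  if (any(ev == "male_exclusive")) {
    other <- any(ev %in% c("both_no_bias", "male_bias"))
    return(if (other) "male_bias" else "male_exclusive")
  }
  if (any(ev == "female_bias")) return("female_bias")
  if (any(ev == "male_bias")) return("male_bias")
  "both_no_bias"
}

# aggregate the non-excluded quotes of one society x modality cell
aggregate_cell <- function(q, society_id, modality) {
  documented <- q[q$proficiency_evidence %in% c("basic", "higher"), ,
                  drop = FALSE]
  if (!nrow(documented)) {
    return(data.frame(
      society_id = society_id, modality = modality,
      presence = "not_documented", proficiency = "not_documented",
      functional_domains = "", special_activities = "",
      gender = "insufficient_info", stringsAsFactors = FALSE
    ))
  }
  proficiency <- if (any(documented$proficiency_evidence == "higher")) {
    "higher"
  } else {
    "basic"
  }
  domains <- unique(unlist(lapply(documented$functional_domains, split_set)))
  specials <- unique(documented$special_activity[
    !is.na(documented$special_activity)])
  # quotes about children's play carry no gender evidence
  gender_rows <- documented[
    !vapply(documented$functional_domains,
            function(d) "child_play" %in% split_set(d), logical(1)), ,
    drop = FALSE]
  gender <- resolve_gender(gender_rows$gender_evidence)
  data.frame(
    society_id = society_id, modality = modality,
    presence = "present", proficiency = proficiency,
    functional_domains = join_set(domains, FUNCTIONAL_DOMAINS),
    special_activities = join_set(specials,
                                  names(SPECIAL_ACTIVITY_MODALITY)),
    gender = gender, stringsAsFactors = FALSE
  )
}

#' Aggregate quote-level codes for one society
#'
#' Applies the deterministic precedence rules that combine quote-level
#' codes into one trait record per modality: a modality is `present` iff at
#' least one non-excluded quote documents basic or higher engagement;
#' proficiency is the maximum over quotes (`basic` is the default, `higher`
#' wins); functional domains and special activities are unions over quotes;
#' gender follows [resolve_gender()]. Modalities with no documenting quote
#' are returned as `not_documented` with no further codes. The aggregation
#' is independent of quote order, and adding a quote can only move codes
#' upward (never removes presence, lowers proficiency, or shrinks a set).
#'
#' @param quotes data.frame of quote records (any societies; excluded rows
#'   are dropped internally).
#' @param society_id the society to aggregate.
#' @return a data.frame with one row per modality (columns
#'   `society_id, modality, presence, proficiency, functional_domains,
#'   special_activities, gender`).
#' @export
aggregate_society_codes <- function(quotes, society_id) {
  q <- quotes[!quotes$excluded & quotes$society_id == society_id, ,
              drop = FALSE]
  out <- lapply(MODALITIES, function(m) {
    aggregate_cell(q[q$modality == m, , drop = FALSE], society_id, m)
  })
  do.call(rbind, out)
}

#' Aggregate quote-level codes for a set of societies
#'
#' @param quotes data.frame of quote records.
#' @param society_ids societies to aggregate; defaults to those appearing
#'   in `quotes`. Societies with no quotes yield all-`not_documented` rows.
#' @return a long data.frame, one row per society and modality; see
#'   [aggregate_society_codes()].
#' @export
aggregate_codes <- function(quotes, society_ids = NULL) {
  ids <- society_ids %||% sort(unique(quotes$society_id))
  q <- quotes[!quotes$excluded & quotes$society_id %in% ids, , drop = FALSE]
  by_soc <- split(q, factor(q$society_id, levels = ids))
  out <- lapply(ids, function(sid) {
    qs <- by_soc[[sid]]
    do.call(rbind, lapply(MODALITIES, function(m) {
      aggregate_cell(qs[qs$modality == m, , drop = FALSE], sid, m)
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Data-level diagnostics on aggregated society codes
#'
#' Reports (never enforces) expectations that hold for well-coded data:
#' every society documented to dive should also be documented to swim
#' (surface swimming is functionally entailed by diving bouts), and the
#' internal consistency of `not_documented` rows (no proficiency, no
#' domains, no special activities, gender `insufficient_info`).
#'
#' @param codes long data.frame from [aggregate_codes()].
#' @return a data.frame of diagnostics (`society_id`, `check`, `message`);
#'   zero rows when no expectation is violated.
#' @export
validate_codes <- function(codes) {
  diags <- list()
  add <- function(society_id, check, message) {
    diags[[length(diags) + 1L]] <<- data.frame(
      society_id = society_id, check = check, message = message,
      stringsAsFactors = FALSE)
  }
  wide_presence <- function(m) {
    rows <- codes[codes$modality == m, ]
    setNames(rows$presence == "present", rows$society_id)
  }
  dive <- wide_presence("diving")
  swim <- wide_presence("swimming")
  for (sid in names(dive)[dive]) {
    if (!isTRUE(swim[[sid]])) {
      add(sid, "dive_implies_swim",
          "society is coded to dive but not to swim")
    }
  }
  nd <- codes[codes$presence == "not_documented", , drop = FALSE]
  bad <- nd$proficiency != "not_documented" |
    nzchar(nd$functional_domains) | nzchar(nd$special_activities) |
    nd$gender != "insufficient_info"
  for (i in which(bad)) {
    add(nd$society_id[i], "not_documented_consistency",
        paste0(nd$modality[i],
               ": not_documented row carries further codes"))
  }
  if (!length(diags)) {
    return(data.frame(society_id = character(0), check = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, diags)
}
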