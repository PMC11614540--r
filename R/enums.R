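# Controlled vocabularies for the locomotor coding scheme.
# All serialized values are canonical snake_case; parsing is case-insensitive.

MODALITIES <- c("running", "climbing", "swimming", "diving")

# fixed modality -> locomotor domain map
MODALITY_DOMAIN <- c(
  running  = "terrestrial",
  climbing = "arboreal",
  swimming = "aquatic",
  diving   = "aquatic"
)

NON_BIPEDAL <- c("climbing", "swimming", "diving")

# quote-level proficiency evidence; society-level uses "not_documented" in
# place of "none" (ordering none/not_documented < basic < higher)
QUOTE_PROFICIENCY <- c("none", "basic", "higher")
CODE_PROFICIENCY <- c("not_documented", "basic", "higher")

FUNCTIONAL_DOMAINS <- c(
  "subsistence", "non_edible_resources", "travel", "child_play",
  "leisure", "ritual", "conflict", "protection", "observation"
)

# special activity -> the single modality it is legal for
SPECIAL_ACTIVITY_MODALITY <- c(
  persistence_hunting = "running",
  honey_climbing      = "climbing",
  underwater_hunting  = "diving"
)

GENDER_EVIDENCE <- c(
  "female_exclusive", "male_exclusive", "female_bias", "male_bias",
  "both_no_bias"
)
GENDER_CODES <- c(GENDER_EVIDENCE, "insufficient_info")

EXCLUSION_REASONS <- c(
  "myth_story_legend", "non_traditional_lifeway", "ambiguous_term"
)

BIOME6 <- c(
  "BorealForestTaiga", "TemperateForest", "TropicalForest",
  "Desert", "Grassland", "Tundra"
)

QUOTE_COLUMNS <- c(
  "society_id", "document_id", "page", "modality", "proficiency_evidence",
  "functional_domains", "special_activity", "gender_evidence",
  "excluded", "exclusion_reason", "note"
)

SOCIETY_COLUMNS <- c(
  "society_id", "name", "dependence_gathering", "dependence_hunting",
  "dependence_fishing", "mht_category", "mean_annual_temp_C",
  "coast_distance_km"
)

CODE_COLUMNS <- c(
  "society_id", "modality", "presence", "proficiency",
  "functional_domains", "special_activities", "gender"
)

#' Is a functional domain applicable to a modality?
#'
#' The coding scheme restricts two domains: "observation" (e.g. scouting
#' from a vantage point) is only coded for climbing, and "travel" only for
#' running and swimming. All other domains apply to every modality.
#'
#' @param domain character vector of functional domains.
#' @param modality character vector of modalities (recycled against
#'   `domain`).
#' @return logical vector.
#' @export
#' @examples
#' domain_applicable("observation", "running")  # FALSE
#' domain_applicable("travel", "swimming")      # TRUE
domain_applicable <- function(domain, modality) {
  stopifnot(all(domain %in% FUNCTIONAL_DOMAINS), all(modality %in% MODALITIES))
  n <- max(length(domain), length(modality))
  domain <- rep_len(domain, n)
  modality <- rep_len(modality, n)
  ok <- rep(TRUE, n)
  ok[domain == "observation" & modality != "climbing"] <- FALSE
  ok[domain == "travel" & !(modality %in% c("running", "swimming"))] <- FALSE
  ok
}
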