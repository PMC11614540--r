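# society x modality codes in wide logical form, used by every summary
presence_matrix <- function(codes) {
  ids <- unique(codes$society_id)
  out <- sapply(MODALITIES, function(m) {
    rows <- codes[codes$modality == m, ]
    setNames(rows$presence == "present", rows$society_id)[ids]
  })
  matrix(out, nrow = length(ids), dimnames = list(ids, MODALITIES))
}

code_column <- function(codes, modality, column) {
  rows <- codes[codes$modality == modality, ]
  setNames(rows[[column]], rows$society_id)
}

#' Load a Major-Habitat-Type to six-biome map
#'
#' The 15-category WWF Major Habitat Type classification is simplified to
#' six biomes (boreal forest/taiga, temperate forest, tropical forest,
#' desert, grassland, tundra). The map ships as an editable two-column
#' tab-delimited file so archive-specific spellings can be accommodated
#' without code changes.
#'
#' @param path path to a `mht_category`/`biome6` table; default the map
#'   shipped with the package.
#' @return a named character vector, names the (normalized) MHT names.
#' @export
read_biome_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "biome_map.tsv",
                                package = "locomotr")
  df <- read_table_checked(path, c("mht_category", "biome6"))
  bad <- setdiff(df$biome6, BIOME6)
  if (length(bad)) {
    stop("unknown biome6 value(s) in map: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  setNames(df$biome6, normalize_mht(df$mht_category))
}

# tolerant normalization of habitat-type names ("&" vs "and", case,
# whitespace, punctuation)
normalize_mht <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("&", "and", x, fixed = TRUE)
  x <- gsub("[^a-z/]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Simplify WWF Major Habitat Types to six biomes
#'
#' @param mht_category character vector of MHT names.
#' @param biome_map optional map from [read_biome_map()].
#' @return character vector of `biome6` values; an unknown habitat name is
#'   a hard error naming it.
#' @export
#' @examples
#' biome_simplify("Tundra")                                      # "Tundra"
#' biome_simplify("Tropical and Subtropical Moist Broadleaf Forests")
biome_simplify <- function(mht_category, biome_map = NULL) {
  map <- biome_map %||% read_biome_map()
  key <- normalize_mht(mht_category)
  unknown <- unique(mht_category[!key %in% names(map)])
  if (length(unknown)) {
    stop("unknown mht_category: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(map[key])
}

#' Modality presence counts with corrected proportions
#'
#' Counts societies documented to engage in each modality, over the full
#' analysis sample, with raw proportions and (when a distance matrix is
#' supplied) phylogenetically corrected proportions using isolation
#' weights over the full sample.
#'
#' @param codes long code table from [aggregate_codes()].
#' @param dist optional patristic distance matrix covering all societies
#'   in `codes`.
#' @param n_resamples,seed passed to [corrected_proportion()].
#' @return a data.frame with one row per modality: `statistic`, `stratum`,
#'   `numerator`, `denominator`, `raw`, `corrected`, `mc_se`.
#' @export
modality_presence_counts <- function(codes, dist = NULL,
                                     n_resamples = DEFAULT_RESAMPLES,
                                     seed = DEFAULT_SEED) {
  pm <- presence_matrix(codes)
  n <- nrow(pm)
  w <- if (!is.null(dist)) isolation_weights(dist, rownames(pm)) else NULL
  rows <- lapply(MODALITIES, function(m) {
    x <- setNames(as.numeric(pm[, m]), rownames(pm))
    corrected <- mc_se <- NA_real_
    if (!is.null(w)) {
      est <- corrected_proportion(x, w, n_resamples,
                                  stage_seed(seed, paste0("presence_", m)),
                                  label = paste0("presence_", m))
      corrected <- est$corrected_value
      mc_se <- est$mc_se
    }
    data.frame(statistic = "modality_presence", stratum = m,
               numerator = as.integer(sum(x)), denominator = n, raw = mean(x),
               corrected = corrected, mc_se = mc_se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Locomotor versatility histogram
#'
#' Distribution of societies over the number of non-bipedal modalities
#' (climbing, swimming, diving) they engage in, 0 to 3, plus the
#' proportion with at least one non-bipedal modality and the proportion
#' engaging all three locomotor domains (terrestrial, arboreal, aquatic).
#' Corrected category shares are computed from a single draw vector, so
#' they sum to one exactly.
#'
#' @inheritParams modality_presence_counts
#' @return a data.frame with strata `"0".."3"` (statistic
#'   `versatility_count`), `any_non_bipedal` and `all_locomotor_domains`.
#' @export
versatility_histogram <- function(codes, dist = NULL,
                                  n_resamples = DEFAULT_RESAMPLES,
                                  seed = DEFAULT_SEED) {
  pm <- presence_matrix(codes)
  n <- nrow(pm)
  k <- rowSums(pm[, NON_BIPEDAL, drop = FALSE])
  kf <- setNames(factor(k, levels = 0:3), rownames(pm))
  any_nb <- setNames(as.numeric(k >= 1), rownames(pm))
  all_dom <- setNames(
    as.numeric(pm[, "running"] & pm[, "climbing"] &
                 (pm[, "swimming"] | pm[, "diving"])), rownames(pm))

  w <- if (!is.null(dist)) isolation_weights(dist, rownames(pm)) else NULL
  hist_rows <- data.frame(
    statistic = "versatility_count", stratum = as.character(0:3),
    numerator = as.integer(table(kf)), denominator = n,
    raw = as.numeric(table(kf)) / n,
    corrected = NA_real_, mc_se = NA_real_, stringsAsFactors = FALSE)
  extra <- data.frame(
    statistic = c("any_non_bipedal", "all_locomotor_domains"),
    stratum = "", numerator = as.integer(c(sum(any_nb), sum(all_dom))),
    denominator = n, raw = c(mean(any_nb), mean(all_dom)),
    corrected = NA_real_, mc_se = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(w)) {
    cd <- corrected_distribution(kf, w, n_resamples,
                                 stage_seed(seed, "versatility"),
                                 label = "versatility_count")
    hist_rows$corrected <- cd$corrected_value
    hist_rows$mc_se <- cd$mc_se
    for (i in seq_len(2)) {
      x <- list(any_nb, all_dom)[[i]]
      est <- corrected_proportion(x, w, n_resamples,
                                  stage_seed(seed, extra$statistic[i]),
                                  label = extra$statistic[i])
      extra$corrected[i] <- est$corrected_value
      extra$mc_se[i] <- est$mc_se
    }
  }
  rbind(hist_rows, extra)
}

#' Modality-overlap (Venn) masses for the non-bipedal modalities
#'
#' Each society falls in exactly one of the eight presence combinations of
#' climbing, swimming and diving; the seven non-empty combinations are the
#' regions of a three-set Venn diagram. Raw masses are society fractions;
#' corrected masses are weighted-resampling shares computed from one draw
#' vector, so regions partition the total mass exactly.
#'
#' @inheritParams modality_presence_counts
#' @return a data.frame with one row per combination (`stratum` such as
#'   `"climbing+swimming"`, with `"none"` for the empty combination).
#' @export
venn_proportions <- function(codes, dist = NULL,
                             n_resamples = DEFAULT_RESAMPLES,
                             seed = DEFAULT_SEED) {
  pm <- presence_matrix(codes)
  combos <- apply(pm[, NON_BIPEDAL, drop = FALSE], 1, function(r) {
    if (!any(r)) "none" else paste(NON_BIPEDAL[r], collapse = "+")
  })
  all_levels <- c("none", vapply(
    seq_len(7), function(i) {
      sel <- as.logical(intToBits(i))[1:3]
      paste(NON_BIPEDAL[sel], collapse = "+")
    }, character(1)))
  f <- setNames(factor(combos, levels = all_levels), rownames(pm))
  n <- nrow(pm)
  out <- data.frame(
    statistic = "venn_region", stratum = all_levels,
    numerator = as.integer(table(f)), denominator = n,
    raw = as.numeric(table(f)) / n,
    corrected = NA_real_, mc_se = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(dist)) {
    w <- isolation_weights(dist, rownames(pm))
    cd <- corrected_distribution(f, w, n_resamples,
                                 stage_seed(seed, "venn"),
                                 label = "venn_region")
    out$corrected <- cd$corrected_value
    out$mc_se <- cd$mc_se
  }
  out
}

#' Ecological breakdown of locomotor engagement
#'
#' Raw (uncorrected) counts of locomotor engagement by biome and
#' proficiency, and temperature summaries: the minimum mean annual
#' temperature at which each modality is present, and how many of the
#' societies below 0 degrees C climb and swim.
#'
#' @param codes long code table from [aggregate_codes()].
#' @param societies society table from [read_societies()] covering the
#'   same societies.
#' @return a list with `by_biome` (biome6 x modality x proficiency counts)
#'   and `temperature` (per-modality minimum temperature of presence plus
#'   sub-zero engagement counts).
#' @export
ecology_breakdown <- function(codes, societies) {
  ids <- unique(codes$society_id)
  soc <- societies[match(ids, societies$society_id), ]
  if (anyNA(soc$society_id)) {
    stop("societies table does not cover all coded societies", call. = FALSE)
  }
  by_biome <- do.call(rbind, lapply(BIOME6, function(b) {
    in_b <- ids[soc$biome6 == b]
    do.call(rbind, lapply(MODALITIES, function(m) {
      prof <- code_column(codes, m, "proficiency")[in_b]
      data.frame(biome6 = b, modality = m,
                 n_societies = length(in_b),
                 n_present = sum(prof != "not_documented"),
                 n_basic = sum(prof == "basic"),
                 n_higher = sum(prof == "higher"),
                 stringsAsFactors = FALSE)
    }))
  }))
  temp <- setNames(soc$mean_annual_temp_C, ids)
  temperature <- do.call(rbind, lapply(MODALITIES, function(m) {
    present <- names(which(code_column(codes, m, "presence") == "present"))
    data.frame(
      modality = m,
      n_present = length(present),
      min_temp_present = if (length(present)) min(temp[present]) else NA_real_,
      n_below_zero_present = sum(temp[present] < 0),
      stringsAsFactors = FALSE)
  }))
  temperature$n_below_zero_total <- sum(temp < 0)
  list(by_biome = by_biome, temperature = temperature)
}

#' Functional-domain proportions by modality
#'
#' For each modality and functional domain, the share of societies with
#' that domain among societies in which the modality is present. Cells
#' outside the applicability mask (observation for anything but climbing;
#' travel for anything but running and swimming) are reported as
#' not-applicable (`NA`), never as zero. A domain found in a masked cell
#' is a data error and is returned in the `"diagnostics"` attribute.
#'
#' @param codes long code table from [aggregate_codes()].
#' @return a data.frame per modality x domain with `numerator`,
#'   `denominator`, `raw`, `applicable`.
#' @export
functional_domain_proportions <- function(codes) {
  diags <- character(0)
  out <- do.call(rbind, lapply(MODALITIES, function(m) {
    rows <- codes[codes$modality == m & codes$presence == "present", ]
    den <- nrow(rows)
    dom_sets <- lapply(rows$functional_domains, split_set)
    do.call(rbind, lapply(FUNCTIONAL_DOMAINS, function(d) {
      applicable <- domain_applicable(d, m)
      num <- sum(vapply(dom_sets, function(s) d %in% s, logical(1)))
      if (!applicable && num > 0) {
        diags <<- c(diags, sprintf(
          "domain '%s' coded in masked cell for modality '%s' (%d societies)",
          d, m, num))
      }
      data.frame(modality = m, domain = d,
                 numerator = if (applicable) num else NA_integer_,
                 denominator = den,
                 raw = if (applicable && den > 0) num / den else NA_real_,
                 applicable = applicable, stringsAsFactors = FALSE)
    }))
  }))
  attr(out, "diagnostics") <- diags
  out
}

#' Higher-proficiency shares within each modality
#'
#' Among the societies in which a modality is present, the share coded to
#' the higher proficiency level, with corrected shares computed using
#' isolation weights re-derived on that subsample (the "respective
#' sample"): weights are never inherited from the full sample.
#'
#' @inheritParams modality_presence_counts
#' @return a data.frame per modality; corrected is `NA` when fewer than
#'   two societies engage in the modality.
#' @export
proficiency_shares <- function(codes, dist = NULL,
                               n_resamples = DEFAULT_RESAMPLES,
                               seed = DEFAULT_SEED) {
  do.call(rbind, lapply(MODALITIES, function(m) {
    prof <- code_column(codes, m, "proficiency")
    present <- names(prof)[prof != "not_documented"]
    x <- setNames(as.numeric(prof[present] == "higher"), present)
    corrected <- mc_se <- NA_real_
    if (!is.null(dist) && length(present) >= 2) {
      w <- isolation_weights(dist, present)
      est <- corrected_proportion(x, w, n_resamples,
                                  stage_seed(seed, paste0("higher_", m)),
                                  label = paste0("higher_", m))
      corrected <- est$corrected_value
      mc_se <- est$mc_se
    }
    data.frame(statistic = "higher_proficiency", stratum = m,
               numerator = as.integer(sum(x)), denominator = length(x),
               raw = if (length(x)) mean(x) else NA_real_,
               corrected = corrected, mc_se = mc_se,
               stringsAsFactors = FALSE)
  }))
}

#' Special subsistence-activity prevalence
#'
#' For persistence hunting (running), honey climbing (climbing) and
#' underwater hunting (diving): among the societies with documented
#' subsistence functionality for the modality, the share engaging in the
#' special activity. Corrected shares use isolation weights re-derived on
#' that denominator subsample.
#'
#' @inheritParams modality_presence_counts
#' @return a data.frame per special activity.
#' @export
special_activity_stats <- function(codes, dist = NULL,
                                   n_resamples = DEFAULT_RESAMPLES,
                                   seed = DEFAULT_SEED) {
  do.call(rbind, lapply(names(SPECIAL_ACTIVITY_MODALITY), function(act) {
    m <- SPECIAL_ACTIVITY_MODALITY[[act]]
    rows <- codes[codes$modality == m & codes$presence == "present", ]
    has_sub <- vapply(rows$functional_domains,
                      function(d) "subsistence" %in% split_set(d), logical(1))
    den_ids <- rows$society_id[has_sub]
    x <- setNames(vapply(
      rows$special_activities[has_sub],
      function(s) as.numeric(act %in% split_set(s)), numeric(1)), den_ids)
    corrected <- mc_se <- NA_real_
    if (!is.null(dist) && length(den_ids) >= 2) {
      w <- isolation_weights(dist, den_ids)
      est <- corrected_proportion(x, w, n_resamples,
                                  stage_seed(seed, act), label = act)
      corrected <- est$corrected_value
      mc_se <- est$mc_se
    }
    data.frame(statistic = "special_activity", stratum = act,
               numerator = as.integer(sum(x)), denominator = length(x),
               raw = if (length(x)) mean(x) else NA_real_,
               corrected = corrected, mc_se = mc_se,
               stringsAsFactors = FALSE)
  }))
}

#' Gender-engagement proportions by modality
#'
#' For each modality, the distribution of society-level gender codes among
#' the societies in which the modality is present *and* sufficient
#' ethnographic information was available (gender not
#' `insufficient_info`). Raw proportions only — no phylogenetic
#' correction is applied to gender statistics. The `"exclusivity"`
#' attribute lists the societies holding any exclusive code in any
#' modality.
#'
#' @param codes long code table from [aggregate_codes()].
#' @return a data.frame per modality x gender category, with the
#'   per-modality denominator; categories partition each denominator.
#' @export
gender_proportions <- function(codes) {
  cats <- GENDER_EVIDENCE
  out <- do.call(rbind, lapply(MODALITIES, function(m) {
    rows <- codes[codes$modality == m & codes$presence == "present", ]
    coded <- rows[rows$gender != "insufficient_info", ]
    den <- nrow(coded)
    counts <- table(factor(coded$gender, levels = cats))
    data.frame(modality = m, gender = cats,
               numerator = as.integer(counts), denominator = den,
               raw = if (den > 0) as.numeric(counts) / den else NA_real_,
               stringsAsFactors = FALSE)
  }))
  excl <- unique(codes$society_id[
    codes$gender %in% c("female_exclusive", "male_exclusive")])
  attr(out, "exclusivity") <- sort(excl)
  out
}

#' Coastal versus inland split for aquatic modalities
#'
#' Among societies engaging in each aquatic modality, how many live inland
#' (strictly more than `threshold_km` from the coast) versus coastal (at
#' or under the threshold). A society at exactly the threshold is coastal.
#'
#' @param codes long code table from [aggregate_codes()].
#' @param societies society table covering the coded societies.
#' @param threshold_km inland threshold in kilometres (default 50).
#' @return a data.frame per aquatic modality with `n_present`, `n_inland`,
#'   `n_coastal`.
#' @export
coastal_split <- function(codes, societies, threshold_km = 50) {
  stopifnot(threshold_km >= 0)
  dist_km <- setNames(societies$coast_distance_km, societies$society_id)
  do.call(rbind, lapply(c("swimming", "diving"), function(m) {
    present <- names(which(code_column(codes, m, "presence") == "present"))
    inland <- sum(dist_km[present] > threshold_km)
    data.frame(modality = m, threshold_km = threshold_km,
               n_present = length(present), n_inland = inland,
               n_coastal = length(present) - inland,
               stringsAsFactors = FALSE)
  }))
}

#' All headline summary statistics for a coded sample
#'
#' Bundles every summary of the analysis into one named list: corrected
#' statistics (modality presence, versatility, overlap regions,
#' higher-proficiency and special-activity shares) use isolation weights
#' derived from `dist` — re-derived per subsample where the denominator is
#' a subsample — while ecology, functional-domain, gender and coastal
#' statistics are raw by design.
#'
#' @param codes long code table from [aggregate_codes()].
#' @param societies society table covering the coded societies.
#' @param dist optional patristic distance matrix; when `NULL`, corrected
#'   columns are `NA`.
#' @param n_resamples,seed resampling controls.
#' @param coast_threshold_km passed to [coastal_split()].
#' @return a named list of data.frames (JSON-serializable).
#' @export
summarize_dataset <- function(codes, societies, dist = NULL,
                              n_resamples = DEFAULT_RESAMPLES,
                              seed = DEFAULT_SEED,
                              coast_threshold_km = 50) {
  eco <- ecology_breakdown(codes, societies)
  list(
    modality_presence = modality_presence_counts(codes, dist, n_resamples, seed),
    versatility = versatility_histogram(codes, dist, n_resamples, seed),
    venn = venn_proportions(codes, dist, n_resamples, seed),
    proficiency = proficiency_shares(codes, dist, n_resamples, seed),
    special_activities = special_activity_stats(codes, dist, n_resamples, seed),
    by_biome = eco$by_biome,
    temperature = eco$temperature,
    functional_domains = functional_domain_proportions(codes),
    gender = gender_proportions(codes),
    coastal = coastal_split(codes, societies, coast_threshold_km)
  )
}
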