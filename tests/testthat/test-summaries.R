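# the worked 4-society sample: one society with climbing+swimming+diving,
# one climbing-only, one swimming-only, one with running only
toy4 <- make_codes(c(s1 = "CSD", s2 = "C", s3 = "S", s4 = ""))

test_that("the shipped biome map is total over the habitat types and strict otherwise", {
  map <- read_biome_map()
  expect_true(all(map %in% locomotr:::BIOME6))
  expect_length(map, 14)
  expect_equal(biome_simplify("Tropical and Subtropical Moist Broadleaf Forests"),
               "TropicalForest")
  expect_equal(biome_simplify("Tropical & Subtropical Moist Broadleaf Forests"),
               "TropicalForest")
  expect_equal(biome_simplify("Tundra"), "Tundra")
  expect_equal(biome_simplify("Boreal Forests/Taiga"), "BorealForestTaiga")
  expect_equal(biome_simplify("Deserts and Xeric Shrublands"), "Desert")
  expect_equal(biome_simplify("Mangroves"), "TropicalForest")
  expect_error(biome_simplify("Cloud City"), "unknown mht_category")
})

test_that("presence counts and versatility histogram match direct enumeration", {
  mp <- modality_presence_counts(toy4)
  counts <- setNames(mp$numerator, mp$stratum)
  expect_equal(counts, c(running = 4, climbing = 2, swimming = 2, diving = 1))
  expect_equal(mp$denominator, rep(4, 4))
  expect_equal(mp$raw, unname(counts) / 4)

  vh <- versatility_histogram(toy4)
  hist <- vh[vh$statistic == "versatility_count", ]
  expect_equal(setNames(hist$numerator, hist$stratum),
               c(`0` = 1, `1` = 2, `2` = 0, `3` = 1))
  expect_equal(sum(hist$numerator), 4)
  any_nb <- vh[vh$statistic == "any_non_bipedal", ]
  expect_equal(any_nb$raw, 3 / 4)
  all_dom <- vh[vh$statistic == "all_locomotor_domains", ]
  expect_equal(all_dom$numerator, 1)  # only s1 spans terrestrial+arboreal+aquatic

  # all-absent and all-present extremes
  none <- make_codes(c(a = "", b = ""))
  vh0 <- versatility_histogram(none)
  expect_equal(vh0$numerator[vh0$stratum == "0"], 2)
  allp <- make_codes(c(a = "CSD", b = "CSD"))
  expect_equal(modality_presence_counts(allp)$raw, rep(1, 4))
})

test_that("Venn regions partition the sample, and diving-only is empty when dive implies swim", {
  vn <- venn_proportions(toy4)
  get <- function(s) vn$raw[vn$stratum == s]
  expect_equal(get("climbing"), 0.25)
  expect_equal(get("swimming"), 0.25)
  expect_equal(get("climbing+swimming+diving"), 0.25)
  expect_equal(get("none"), 0.25)
  expect_equal(sum(vn$raw), 1)
  # region masses sum to the any-non-bipedal mass
  vh <- versatility_histogram(toy4)
  expect_equal(sum(vn$raw[vn$stratum != "none"]),
               vh$raw[vh$statistic == "any_non_bipedal"])
  # dive-implies-swim data never populate the diving-only region
  expect_equal(get("diving"), 0)
})

test_that("corrected summary columns agree with the analytic oracle on a weighted toy", {
  tr <- ape::read.tree(text = "((s1:1,s2:1):4,(s3:2.5,s4:2.5):2.5);")
  d <- patristic_distances(tr)
  w <- isolation_weights(d)
  wv <- setNames(w$weight, w$society_id)
  mp <- modality_presence_counts(toy4, d, n_resamples = 2e4, seed = 5)
  pm <- c(s1 = 1, s2 = 1, s3 = 0, s4 = 0)  # climbing presence
  oracle <- analytic_weighted_value(pm, wv)
  row <- mp[mp$stratum == "climbing", ]
  expect_lte(abs(row$corrected - oracle), 4 * row$mc_se)
  # corrected histogram shares still sum to one exactly
  vh <- versatility_histogram(toy4, d, n_resamples = 2e4, seed = 5)
  expect_equal(sum(vh$corrected[vh$statistic == "versatility_count"]), 1)
  vn <- venn_proportions(toy4, d, n_resamples = 2e4, seed = 5)
  expect_equal(sum(vn$corrected), 1)
})

test_that("ecology breakdown reports biome counts and temperature minima", {
  soc <- rbind(
    society_row(society_id = "s1", mht_category = "Mangroves",
                mean_annual_temp_C = 26),
    society_row(society_id = "s2", mht_category = "Tundra",
                mean_annual_temp_C = -3),
    society_row(society_id = "s3", mht_category = "Temperate Conifer Forests",
                mean_annual_temp_C = 4),
    society_row(society_id = "s4", mht_category = "Tundra",
                mean_annual_temp_C = -12))
  soc$biome6 <- biome_simplify(soc$mht_category)
  eco <- ecology_breakdown(toy4, soc)

  tf_dive <- eco$by_biome[eco$by_biome$biome6 == "TropicalForest" &
                            eco$by_biome$modality == "diving", ]
  expect_equal(tf_dive$n_present, 1)
  other_dive <- eco$by_biome[eco$by_biome$biome6 != "TropicalForest" &
                               eco$by_biome$modality == "diving", ]
  expect_equal(sum(other_dive$n_present), 0)
  # biome totals add up to whole-sample presence counts
  mp <- modality_presence_counts(toy4)
  for (m in locomotr:::MODALITIES) {
    expect_equal(sum(eco$by_biome$n_present[eco$by_biome$modality == m]),
                 mp$numerator[mp$stratum == m])
  }

  temp <- eco$temperature
  # swimmers are s1 (26) and s3 (4): minimum 4; climbers s1 (26), s2 (-3)
  expect_equal(temp$min_temp_present[temp$modality == "swimming"], 4)
  expect_equal(temp$min_temp_present[temp$modality == "climbing"], -3)
  expect_equal(temp$min_temp_present[temp$modality == "running"], -12)
  expect_equal(temp$n_below_zero_present[temp$modality == "climbing"], 1)
  expect_equal(unique(temp$n_below_zero_total), 2)
})

test_that("functional-domain proportions respect the applicability mask", {
  codes <- make_codes(c(a = "C", b = "C", c = "C"))
  codes$functional_domains[codes$modality == "climbing" &
                             codes$society_id %in% c("a", "b")] <-
    "subsistence"
  fd <- functional_domain_proportions(codes)
  row <- fd[fd$modality == "climbing" & fd$domain == "subsistence", ]
  expect_equal(row$raw, 2 / 3)
  expect_equal(row$denominator, 3)

  # observation is applicable only to climbing; travel never to climbing
  expect_true(fd$applicable[fd$modality == "climbing" &
                              fd$domain == "observation"])
  expect_false(any(fd$applicable[fd$modality != "climbing" &
                                   fd$domain == "observation"]))
  expect_false(fd$applicable[fd$modality == "climbing" &
                               fd$domain == "travel"])
  masked <- fd[!fd$applicable, ]
  expect_true(all(is.na(masked$raw)))  # not-applicable, never zero

  # a domain in a masked cell is reported as a data error
  bad <- codes
  bad$functional_domains[bad$modality == "climbing" &
                           bad$society_id == "a"] <- "travel"
  expect_match(attr(functional_domain_proportions(bad), "diagnostics"),
               "masked cell", all = FALSE)

  # a modality absent everywhere has empty denominators
  expect_equal(unique(fd$denominator[fd$modality == "diving"]), 0)
})

test_that("special-activity shares use the subsistence denominator with re-derived weights", {
  codes <- make_codes(c(a = "C", b = "C", c = "C", d = "C"))
  idx <- codes$modality == "climbing" & codes$society_id != "d"
  codes$functional_domains[idx] <- "subsistence"
  codes$special_activities[codes$modality == "climbing" &
                             codes$society_id == "a"] <- "honey_climbing"
  tr <- ape::read.tree(text = "((a:1,b:1):4,(c:2.5,d:2.5):2.5);")
  d <- patristic_distances(tr)
  sa <- special_activity_stats(codes, d, n_resamples = 2e4, seed = 3)
  honey <- sa[sa$stratum == "honey_climbing", ]
  expect_equal(honey$denominator, 3)  # d lacks subsistence functionality
  expect_equal(honey$raw, 1 / 3)
  # oracle: weights re-derived on {a, b, c}, not renormalized full weights
  w_sub <- isolation_weights(d, c("a", "b", "c"))
  oracle <- analytic_weighted_value(c(a = 1, b = 0, c = 0),
                                    setNames(w_sub$weight, w_sub$society_id))
  expect_lte(abs(honey$corrected - oracle), 4 * honey$mc_se)
  # all subsistence-engagers practice the activity -> exactly 1
  all_h <- codes
  all_h$special_activities[idx] <- "honey_climbing"
  sa2 <- special_activity_stats(all_h, d, n_resamples = 5e3, seed = 3)
  expect_equal(sa2[sa2$stratum == "honey_climbing", "corrected"], 1)
})

test_that("gender proportions partition the sufficiently-documented denominator", {
  codes <- make_codes(c(a = "S", b = "S", c = "S", d = "S"),
                      gender = "both_no_bias")
  codes$gender[codes$modality == "swimming" & codes$society_id == "a"] <-
    "male_bias"
  codes$gender[codes$modality == "running"] <- "insufficient_info"
  gp <- gender_proportions(codes)
  swim <- gp[gp$modality == "swimming", ]
  expect_equal(unique(swim$denominator), 4)
  expect_equal(swim$raw[swim$gender == "male_bias"], 0.25)
  expect_equal(sum(swim$numerator), unique(swim$denominator))
  # insufficient_info excluded from the denominator entirely
  run <- gp[gp$modality == "running", ]
  expect_equal(unique(run$denominator), 0)
  expect_true(all(is.na(run$raw)))
  # exclusivity roster
  codes$gender[codes$modality == "swimming" & codes$society_id == "b"] <-
    "female_exclusive"
  expect_equal(attr(gender_proportions(codes), "exclusivity"), "b")
})

test_that("coastal split uses a strict inland inequality", {
  soc <- rbind(society_row(society_id = "s1", coast_distance_km = 10),
               society_row(society_id = "s2", coast_distance_km = 60),
               society_row(society_id = "s3", coast_distance_km = 200),
               society_row(society_id = "s4", coast_distance_km = 50))
  soc$biome6 <- "Tundra"
  codes <- make_codes(c(s1 = "S", s2 = "S", s3 = "S", s4 = "S"))
  cs <- coastal_split(codes, soc)
  swim <- cs[cs$modality == "swimming", ]
  expect_equal(swim$n_present, 4)
  expect_equal(swim$n_inland, 2)      # 60 and 200 km
  expect_equal(swim$n_coastal, 2)     # 10 km, and exactly 50 km is coastal
  zero <- coastal_split(make_codes(c(s1 = "S")), soc[1, ])
  expect_equal(zero$n_inland[zero$modality == "swimming"], 0)
})
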