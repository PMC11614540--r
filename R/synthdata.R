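#' Configuration for the synthetic-data generator
#'
#' Returns a validated configuration with defaults that mirror the study
#' conditions of the cross-cultural sample the pipeline targets: 53
#' societies, with half the tips concentrated in one shallow recent clade
#' (emulating the over-representation of one world region in the sample),
#' biome frequencies and biome-specific temperature models spanning tundra
#' to tropical forest, trait presence probabilities that shut off aquatic
#' modalities below cold cutoffs, and a documentation model that by
#' default is a faithful observer (every true trait yields at least one
#' quote; gender evidence for female engagement is never dropped) so the
#' aggregate of the generated quotes reproduces the ground-truth codes
#' exactly. Documentation probability, myth rate and female-evidence
#' dropout are the dials for bias experiments.
#'
#' @param n_societies number of societies/tips (default 53).
#' @param clustered_clade_fraction fraction of tips inside the one shallow
#'   clade, in \[0, 1) (default 0.5).
#' @param tree_depth root-to-tip depth of the tree, in time units
#'   (default 60).
#' @param clade_age_scale depth of the clustered clade relative to
#'   `tree_depth`, in (0, 1) (default 0.1).
#' @param biome_probs named probabilities over the six biomes.
#' @param temp_model per-biome `mean`/`sd` of mean annual temperature (deg C).
#' @param trait_model per modality: `base_p` presence probability and
#'   `cold_cutoff` (deg C) below which the modality is absent (`-Inf` for
#'   none). Diving presence forces swimming presence.
#' @param higher_p per modality, probability a present modality is coded
#'   to higher proficiency.
#' @param domain_probs per modality, named probabilities that each
#'   applicable functional domain is in the society's true domain set.
#' @param special_p per special activity, probability given subsistence
#'   functionality in the matching modality.
#' @param gender_probs per modality, probabilities over the six gender
#'   codes for present modalities.
#' @param p_document probability a true society x modality trait is
#'   documented at all (default 1).
#' @param extra_quote_mean mean number of additional quotes beyond the
#'   first per documented trait (Poisson; default 1).
#' @param myth_rate per society x modality probability of one additional
#'   excluded myth/legend quote (default 0.05).
#' @param none_quote_rate per society x modality probability of one quote
#'   with no proficiency evidence (default 0.05).
#' @param female_dropout probability that a piece of evidence documenting
#'   female engagement is omitted by the ethnographer (default 0).
#' @param seed integer seed governing every random choice (default
#'   20242553).
#' @return a validated list of class `"generator_config"`; round-trips
#'   through [write_generator_config()] / [read_generator_config()].
#' @export
generator_config <- function(
    n_societies = 53,
    clustered_clade_fraction = 0.5,
    tree_depth = 60,
    clade_age_scale = 0.1,
    biome_probs = c(BorealForestTaiga = 0.17, TemperateForest = 0.17,
                    TropicalForest = 0.30, Desert = 0.09,
                    Grassland = 0.15, Tundra = 0.12),
    temp_model = list(
      BorealForestTaiga = c(mean = -5, sd = 4),
      TemperateForest = c(mean = 8, sd = 4),
      TropicalForest = c(mean = 25, sd = 2),
      Desert = c(mean = 20, sd = 5),
      Grassland = c(mean = 17, sd = 5),
      Tundra = c(mean = -11, sd = 4)),
    trait_model = list(
      running = c(base_p = 1, cold_cutoff = -Inf),
      climbing = c(base_p = 0.88, cold_cutoff = -10),
      swimming = c(base_p = 0.88, cold_cutoff = -3),
      diving = c(base_p = 0.5, cold_cutoff = 5)),
    higher_p = c(running = 0.3, climbing = 0.65, swimming = 0.18,
                 diving = 0.2),
    domain_probs = list(
      running = c(subsistence = 0.66, non_edible_resources = 0.1,
                  travel = 0.3, child_play = 0.45, leisure = 0.5,
                  ritual = 0.3, conflict = 0.35, protection = 0.15),
      climbing = c(subsistence = 0.7, non_edible_resources = 0.3,
                   child_play = 0.3, leisure = 0.25, ritual = 0.1,
                   conflict = 0.1, protection = 0.2, observation = 0.25),
      swimming = c(subsistence = 0.25, non_edible_resources = 0.1,
                   travel = 0.45, child_play = 0.5, leisure = 0.5,
                   ritual = 0.1, conflict = 0.2, protection = 0.1),
      diving = c(subsistence = 0.65, non_edible_resources = 0.2,
                 child_play = 0.4, leisure = 0.35, ritual = 0.05,
                 conflict = 0.05, protection = 0.05)),
    special_p = c(persistence_hunting = 0.5, honey_climbing = 0.45,
                  underwater_hunting = 0.45),
    gender_probs = list(
      running = c(female_exclusive = 0.00, male_exclusive = 0.01,
                  female_bias = 0.01, male_bias = 0.08,
                  both_no_bias = 0.45, insufficient_info = 0.45),
      climbing = c(female_exclusive = 0.005, male_exclusive = 0.04,
                   female_bias = 0.005, male_bias = 0.13,
                   both_no_bias = 0.17, insufficient_info = 0.65),
      swimming = c(female_exclusive = 0.01, male_exclusive = 0.02,
                   female_bias = 0.01, male_bias = 0.03,
                   both_no_bias = 0.60, insufficient_info = 0.33),
      diving = c(female_exclusive = 0.02, male_exclusive = 0.03,
                 female_bias = 0.02, male_bias = 0.06,
                 both_no_bias = 0.32, insufficient_info = 0.55)),
    p_document = 1,
    extra_quote_mean = 1,
    myth_rate = 0.05,
    none_quote_rate = 0.05,
    female_dropout = 0,
    seed = DEFAULT_SEED) {
  cfg <- list(
    n_societies = as.integer(n_societies),
    clustered_clade_fraction = clustered_clade_fraction,
    tree_depth = tree_depth, clade_age_scale = clade_age_scale,
    biome_probs = biome_probs, temp_model = temp_model,
    trait_model = trait_model, higher_p = higher_p,
    domain_probs = domain_probs, special_p = special_p,
    gender_probs = gender_probs, p_document = p_document,
    extra_quote_mean = extra_quote_mean, myth_rate = myth_rate,
    none_quote_rate = none_quote_rate, female_dropout = female_dropout,
    seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(
    cfg$n_societies >= 4,
    cfg$clustered_clade_fraction >= 0, cfg$clustered_clade_fraction < 1,
    cfg$tree_depth > 0,
    cfg$clade_age_scale > 0, cfg$clade_age_scale < 1,
    setequal(names(cfg$biome_probs), BIOME6),
    abs(sum(cfg$biome_probs) - 1) < 1e-6,
    setequal(names(cfg$temp_model), BIOME6),
    setequal(names(cfg$trait_model), MODALITIES),
    all(vapply(cfg$trait_model, function(x) x[["base_p"]], 1) >= 0),
    all(vapply(cfg$trait_model, function(x) x[["base_p"]], 1) <= 1),
    cfg$p_document >= 0, cfg$p_document <= 1,
    cfg$myth_rate >= 0, cfg$myth_rate <= 1,
    cfg$none_quote_rate >= 0, cfg$none_quote_rate <= 1,
    cfg$female_dropout >= 0, cfg$female_dropout <= 1,
    all(unlist(cfg$special_p) >= 0), all(unlist(cfg$special_p) <= 1),
    all(unlist(cfg$domain_probs) >= 0), all(unlist(cfg$domain_probs) <= 1)
  )
  for (m in MODALITIES) {
    gp <- cfg$gender_probs[[m]]
    stopifnot(setequal(names(gp), GENDER_CODES), abs(sum(gp) - 1) < 1e-6)
    stopifnot(all(names(cfg$domain_probs[[m]]) %in% FUNCTIONAL_DOMAINS))
    stopifnot(all(domain_applicable(names(cfg$domain_probs[[m]]), m)))
  }
  invisible(cfg)
}

#' @rdname generator_config
#' @param cfg a `generator_config`.
#' @param path a YAML file path.
#' @export
write_generator_config <- function(cfg, path) {
  # named numeric vectors must become maps, or YAML drops the names
  out <- unclass(cfg)
  as_map <- function(x) as.list(x)
  for (nm in c("biome_probs", "higher_p", "special_p")) {
    out[[nm]] <- as_map(out[[nm]])
  }
  for (nm in c("temp_model", "trait_model", "domain_probs", "gender_probs")) {
    out[[nm]] <- lapply(out[[nm]], as_map)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$biome_probs <- unlist(raw$biome_probs)
  raw$temp_model <- lapply(raw$temp_model, unlist)
  raw$trait_model <- lapply(raw$trait_model, unlist)
  raw$higher_p <- unlist(raw$higher_p)
  raw$domain_probs <- lapply(raw$domain_probs, unlist)
  raw$special_p <- unlist(raw$special_p)
  raw$gender_probs <- lapply(raw$gender_probs, unlist)
  do.call(generator_config, raw)
}

# ultrametric tree with a fraction of tips inside one rescaled shallow
# clade, built by joining two coalescent subtrees under a common root
simulate_clustered_tree <- function(n, clade_fraction, depth, clade_scale) {
  n_in <- round(clade_fraction * n)
  ids <- sprintf("soc_%03d", seq_len(n))
  scale_to_depth <- function(tr, target) {
    tr$edge.length <- tr$edge.length *
      (target / max(ape::node.depth.edgelength(tr)))
    tr
  }
  if (n_in < 2 || n - n_in < 2) {
    tr <- scale_to_depth(ape::rcoal(n, tip.label = ids), depth)
    return(list(tree = tr, clade_tips = character(0)))
  }
  out_ids <- ids[seq_len(n - n_in)]
  in_ids <- ids[(n - n_in + 1):n]
  t_out <- scale_to_depth(ape::rcoal(n - n_in, tip.label = out_ids),
                          depth * 0.95)
  t_in <- scale_to_depth(ape::rcoal(n_in, tip.label = in_ids),
                         depth * clade_scale)
  nwk <- sprintf("(%s:%.10g,%s:%.10g);",
                 sub(";$", "", ape::write.tree(t_out)), depth * 0.05,
                 sub(";$", "", ape::write.tree(t_in)),
                 depth * (1 - clade_scale))
  list(tree = ape::read.tree(text = nwk), clade_tips = in_ids)
}

draw_society_table <- function(cfg, ids, biome_map) {
  n <- length(ids)
  biome <- sample(names(cfg$biome_probs), n, replace = TRUE,
                  prob = cfg$biome_probs)
  temp <- vapply(biome, function(b) {
    tm <- cfg$temp_model[[b]]
    round(rnorm(1, tm[["mean"]], tm[["sd"]]), 1)
  }, numeric(1))
  coast <- round(rexp(n, 1 / 120), 1)
  total_dep <- runif(n, 60, 95)
  parts <- matrix(stats::rgamma(3 * n, shape = 2), ncol = 3)
  parts <- parts / rowSums(parts) * total_dep
  parts <- floor(parts * 10) / 10
  # invert the biome map to draw a concrete habitat-type name
  mht_names <- read_biome_map_names(biome_map)
  mht <- vapply(biome, function(b) {
    pool <- mht_names$mht_category[mht_names$biome6 == b]
    pool[sample.int(length(pool), 1)]
  }, character(1))
  data.frame(
    society_id = ids, name = paste0("Society ", toupper(ids)),
    dependence_gathering = parts[, 1], dependence_hunting = parts[, 2],
    dependence_fishing = parts[, 3], mht_category = mht,
    mean_annual_temp_C = unname(temp), coast_distance_km = coast,
    biome6 = biome, stringsAsFactors = FALSE)
}

# biome map as a two-column frame with original (unnormalized) names
read_biome_map_names <- function(path = NULL) {
  path <- path %||% system.file("extdata", "biome_map.tsv",
                                package = "locomotr")
  read_table_checked(path, c("mht_category", "biome6"))
}

draw_truth_codes <- function(cfg, societies) {
  rows <- list()
  for (i in seq_len(nrow(societies))) {
    sid <- societies$society_id[i]
    temp <- societies$mean_annual_temp_C[i]
    present <- setNames(logical(4), MODALITIES)
    for (m in MODALITIES) {
      tm <- cfg$trait_model[[m]]
      p <- if (temp < tm[["cold_cutoff"]]) 0 else tm[["base_p"]]
      present[m] <- runif(1) < p
    }
    if (present["diving"]) present["swimming"] <- TRUE
    for (m in MODALITIES) {
      if (!present[m]) {
        rows[[length(rows) + 1L]] <- data.frame(
          society_id = sid, modality = m, presence = "not_documented",
          proficiency = "not_documented", functional_domains = "",
          special_activities = "", gender = "insufficient_info",
          stringsAsFactors = FALSE)
        next
      }
      prof <- if (runif(1) < cfg$higher_p[[m]]) "higher" else "basic"
      dp <- cfg$domain_probs[[m]]
      doms <- names(dp)[runif(length(dp)) < dp]
      specials <- character(0)
      if ("subsistence" %in% doms) {
        acts <- names(SPECIAL_ACTIVITY_MODALITY)[
          SPECIAL_ACTIVITY_MODALITY == m]
        specials <- acts[runif(length(acts)) < cfg$special_p[acts]]
      }
      gender <- sample(GENDER_CODES, 1, prob = cfg$gender_probs[[m]][GENDER_CODES])
      rows[[length(rows) + 1L]] <- data.frame(
        society_id = sid, modality = m, presence = "present",
        proficiency = prof,
        functional_domains = join_set(doms, FUNCTIONAL_DOMAINS),
        special_activities = join_set(specials,
                                      names(SPECIAL_ACTIVITY_MODALITY)),
        gender = gender, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_quote_row <- function(sid, m) {
  data.frame(
    society_id = sid, document_id = "", page = "", modality = m,
    proficiency_evidence = "none", functional_domains = "",
    special_activity = NA_character_, gender_evidence = NA_character_,
    excluded = FALSE, exclusion_reason = NA_character_, note = "",
    stringsAsFactors = FALSE)
}

# quotes for one documented society x modality trait; quote 1 carries the
# gender evidence and never the child_play domain, so the aggregate of a
# faithful corpus reproduces the truth exactly
quotes_for_cell <- function(cfg, sid, truth_row, doc_counter) {
  m <- truth_row$modality
  n_q <- 1L + rpois(1, cfg$extra_quote_mean)
  doms <- split_set(truth_row$functional_domains)
  gender <- truth_row$gender
  if (n_q < 2 && "child_play" %in% doms && gender != "insufficient_info") {
    n_q <- 2L
  }
  dom_assign <- vector("list", n_q)
  for (d in doms) {
    j <- if (d == "child_play" && n_q >= 2) {
      1L + sample.int(n_q - 1L, 1)
    } else {
      sample.int(n_q, 1)
    }
    dom_assign[[j]] <- c(dom_assign[[j]], d)
  }
  prof <- rep("basic", n_q)
  if (truth_row$proficiency == "higher") {
    prof[sample.int(n_q, 1)] <- "higher"
    prof[prof == "basic"] <- ifelse(runif(sum(prof == "basic")) < 0.3,
                                    "higher", "basic")
  }
  specials <- rep(NA_character_, n_q)
  for (act in split_set(truth_row$special_activities)) {
    j <- sample.int(n_q, 1)
    specials[j] <- act
    dom_assign[[j]] <- unique(c(dom_assign[[j]], "subsistence"))
  }
  ev <- rep(NA_character_, n_q)
  if (gender != "insufficient_info") {
    # drop evidence revealing female engagement with the configured
    # probability (ethnographic under-documentation of women)
    reveals_female <- gender %in% c("female_exclusive", "female_bias",
                                    "both_no_bias", "male_bias")
    if (!(reveals_female && runif(1) < cfg$female_dropout)) {
      ev[1] <- gender
    }
  }
  out <- do.call(rbind, lapply(seq_len(n_q), function(j) {
    r <- empty_quote_row(sid, m)
    r$document_id <- sprintf("doc_%05d", doc_counter + j)
    r$page <- as.character(sample.int(400, 1))
    r$proficiency_evidence <- prof[j]
    r$functional_domains <- join_set(dom_assign[[j]] %||% character(0),
                                     FUNCTIONAL_DOMAINS)
    r$special_activity <- specials[j]
    r$gender_evidence <- ev[j]
    r
  }))
  out
}

#' Generate a synthetic study dataset
#'
#' Draws, under a single seed, (i) an ultrametric time tree with one
#' deliberately over-represented shallow clade, (ii) a society covariate
#' table with biome-conditional temperatures, coast distances and
#' subsistence-dependence percentages, (iii) ground-truth society x
#' modality trait codes from the ecological trait model, and (iv) a
#' quote-level corpus sampled from the truth under the documentation
#' model. With the faithful-observer defaults (documentation probability
#' 1, female-evidence dropout 0) aggregating the quotes reproduces the
#' truth codes exactly; myth-flagged quotes are additional excluded rows
#' and touch nothing downstream.
#'
#' @param cfg a [generator_config()].
#' @param dir optional directory; when given, writes `tree.nwk`,
#'   `societies.tsv`, `truth_codes.tsv`, `quotes.tsv` and `config.yml`
#'   (byte-identical across reruns with the same config).
#' @return a list: `tree` (ape phylo), `societies`, `truth_codes`,
#'   `quotes`, `clade_tips`, `config`.
#' @export
generate_dataset <- function(cfg = generator_config(), dir = NULL) {
  validate_generator_config(cfg)
  res <- with_preserved_seed(cfg$seed, {
    tr <- simulate_clustered_tree(cfg$n_societies,
                                  cfg$clustered_clade_fraction,
                                  cfg$tree_depth, cfg$clade_age_scale)
    societies <- draw_society_table(cfg, tr$tree$tip.label, NULL)
    truth <- draw_truth_codes(cfg, societies)
    quotes <- list()
    doc_counter <- 0L
    for (i in seq_len(nrow(truth))) {
      row <- truth[i, ]
      if (row$presence == "present" && runif(1) < cfg$p_document) {
        q <- quotes_for_cell(cfg, row$society_id, row, doc_counter)
        doc_counter <- doc_counter + nrow(q)
        quotes[[length(quotes) + 1L]] <- q
      }
      if (runif(1) < cfg$none_quote_rate) {
        r <- empty_quote_row(row$society_id, row$modality)
        doc_counter <- doc_counter + 1L
        r$document_id <- sprintf("doc_%05d", doc_counter)
        r$note <- "no engagement documented"
        quotes[[length(quotes) + 1L]] <- r
      }
      if (runif(1) < cfg$myth_rate) {
        r <- empty_quote_row(row$society_id, row$modality)
        doc_counter <- doc_counter + 1L
        r$document_id <- sprintf("doc_%05d", doc_counter)
        r$proficiency_evidence <- "basic"
        r$excluded <- TRUE
        r$exclusion_reason <- "myth_story_legend"
        r$note <- "mythical passage"
        quotes[[length(quotes) + 1L]] <- r
      }
    }
    quotes <- do.call(rbind, quotes)
    rownames(quotes) <- NULL
    list(tree = tr$tree, societies = societies, truth_codes = truth,
         quotes = quotes, clade_tips = tr$clade_tips, config = cfg)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ape::write.tree(res$tree, file.path(dir, "tree.nwk"))
    write_societies(res$societies, file.path(dir, "societies.tsv"))
    write_tsv(res$truth_codes, file.path(dir, "truth_codes.tsv"))
    write_quotes(res$quotes, file.path(dir, "quotes.tsv"))
    write_generator_config(cfg, file.path(dir, "config.yml"))
  }
  res
}

#' Degrade a quote corpus by under-documentation
#'
#' Models the ethnographic documentation filter: for each society x
#' modality cell, all quotes are retained with probability `p` and dropped
#' otherwise (all-or-none, since one ethnographer failing to note a
#' behaviour usually loses every mention). Used to trace how presence
#' counts decay as documentation worsens.
#'
#' @param quotes data.frame of quote records.
#' @param p retention probability in \[0, 1\].
#' @param seed integer RNG seed.
#' @return the retained subset of `quotes`.
#' @export
degrade_quotes <- function(quotes, p, seed = DEFAULT_SEED) {
  stopifnot(p >= 0, p <= 1)
  cells <- unique(quotes[c("society_id", "modality")])
  keep <- with_preserved_seed(seed, runif(nrow(cells)) < p)
  kept_keys <- paste(cells$society_id, cells$modality)[keep]
  out <- quotes[paste(quotes$society_id, quotes$modality) %in% kept_keys, ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}
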