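# fixtures and independent oracles built in code

# one valid quote row with overridable fields
quote_row <- function(...) {
  base <- data.frame(
    society_id = "s1", document_id = "d1", page = "1",
    modality = "running", proficiency_evidence = "basic",
    functional_domains = "", special_activity = NA_character_,
    gender_evidence = NA_character_, excluded = FALSE,
    exclusion_reason = NA_character_, note = "",
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

quotes_df <- function(...) do.call(rbind, list(...))

society_row <- function(...) {
  base <- data.frame(
    society_id = "s1", name = "Toy society",
    dependence_gathering = 40, dependence_hunting = 20,
    dependence_fishing = 10, mht_category = "Tundra",
    mean_annual_temp_C = -10, coast_distance_km = 5,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# society codes from a compact spec: named character vector, each value a
# string over the letters C (climbing), S (swimming), D (diving); running
# is always present
make_codes <- function(spec, gender = NULL) {
  letter <- c(climbing = "C", swimming = "S", diving = "D")
  rows <- lapply(names(spec), function(sid) {
    do.call(rbind, lapply(locomotr:::MODALITIES, function(m) {
      present <- m == "running" || grepl(letter[[m]], spec[[sid]], fixed = TRUE)
      g <- if (!is.null(gender) && present) gender else "insufficient_info"
      data.frame(
        society_id = sid, modality = m,
        presence = if (present) "present" else "not_documented",
        proficiency = if (present) "basic" else "not_documented",
        functional_domains = "", special_activities = "",
        gender = if (present) g else "insufficient_info",
        stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

# brute-force patristic distance: root-to-tip depths and MRCA from the raw
# edge table, independent of ape's cophenetic machinery
bf_patristic <- function(tree, a, b) {
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(tip) {
    node <- which(tree$tip.label == tip)
    nodes <- node
    depth <- c(0)
    while (parent[node] != 0) {
      depth <- c(depth, depth[length(depth)] + elen[node])
      node <- parent[node]
      nodes <- c(nodes, node)
    }
    setNames(depth, nodes)
  }
  pa <- path_to_root(a)
  pb <- path_to_root(b)
  shared <- intersect(names(pa), names(pb))
  min(pa[shared] + pb[shared])
}

# truth-functional gender oracle: aggregate engagement/denial claims per
# gender, then read the code off the claim table
oracle_gender <- function(ev) {
  ev <- ev[!is.na(ev)]
  if (!length(ev)) return("insufficient_info")
  engages <- function(g) {
    any(vapply(ev, function(v) {
      switch(v,
             female_exclusive = g == "female",
             male_exclusive = g == "male",
             female_bias = TRUE, male_bias = TRUE, both_no_bias = TRUE)
    }, logical(1)))
  }
  dir_female <- any(ev %in% c("female_exclusive", "female_bias"))
  dir_male <- any(ev %in% c("male_exclusive", "male_bias"))
  if (dir_female && dir_male) return("conflict")
  if (any(ev == "female_exclusive")) {
    others <- ev[ev != "female_exclusive"]
    male_engaged <- length(others) > 0 && {
      any(vapply(others, function(v) switch(
        v, female_bias = TRUE, male_bias = TRUE, both_no_bias = TRUE,
        male_exclusive = TRUE, female_exclusive = FALSE), logical(1)))
    }
    return(if (male_engaged) "female_bias" else "female_exclusive")
  }
  if (any(ev == "male_exclusive")) {
    others <- ev[ev != "male_exclusive"]
    female_engaged <- length(others) > 0 && {
      any(vapply(others, function(v) switch(
        v, female_bias = TRUE, male_bias = TRUE, both_no_bias = TRUE,
        female_exclusive = TRUE, male_exclusive = FALSE), logical(1)))
    }
    return(if (female_engaged) "male_bias" else "male_exclusive")
  }
  if (dir_female) return("female_bias")
  if (dir_male) return("male_bias")
  "both_no_bias"
}

# every multiset of gender-evidence values up to a given size
gender_multisets <- function(max_size = 3) {
  vals <- locomotr:::GENDER_EVIDENCE
  out <- list()
  for (k in seq_len(max_size)) {
    grid <- do.call(expand.grid,
                    c(rep(list(vals), k), stringsAsFactors = FALSE))
    keys <- apply(grid, 1, function(r) paste(sort(r), collapse = "|"))
    out <- c(out, lapply(unique(keys),
                         function(key) strsplit(key, "|", fixed = TRUE)[[1]]))
  }
  out
}

# implied quote corpus of an aggregated code table (for idempotence):
# one quote carrying proficiency/domains/specials, one carrying gender
codes_to_quotes <- function(codes) {
  rows <- list()
  for (i in seq_len(nrow(codes))) {
    r <- codes[i, ]
    if (r$presence != "present") next
    rows[[length(rows) + 1L]] <- quote_row(
      society_id = r$society_id, modality = r$modality,
      proficiency_evidence = r$proficiency,
      functional_domains = r$functional_domains,
      special_activity = if (nzchar(r$special_activities))
        strsplit(r$special_activities, ";")[[1]][1] else NA_character_)
    extra <- setdiff(strsplit(r$special_activities, ";")[[1]],
                     strsplit(r$special_activities, ";")[[1]][1])
    for (act in extra[nzchar(extra)]) {
      rows[[length(rows) + 1L]] <- quote_row(
        society_id = r$society_id, modality = r$modality,
        proficiency_evidence = "basic", special_activity = act)
    }
    if (r$gender != "insufficient_info") {
      rows[[length(rows) + 1L]] <- quote_row(
        society_id = r$society_id, modality = r$modality,
        proficiency_evidence = "basic", gender_evidence = r$gender)
    }
  }
  do.call(rbind, rows)
}
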