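#' Read a time-calibrated society tree
#'
#' Loads a rooted Newick tree whose tips are society identifiers and whose
#' branch lengths are in consistent time units. Branch lengths must be
#' present and non-negative and tip labels unique. When `society_ids` is
#' supplied, every analyzed society must map to a tip (a missing society is
#' a hard error — silently dropping or reweighting it would change the
#' estimand); tips with no matching society are reported via an attribute
#' and a message. A diagnostic warning is emitted when root-to-tip depths
#' vary by more than 1% (the tree need not be ultrametric, but large
#' departures usually indicate unit problems).
#'
#' @param path path to a Newick file.
#' @param society_ids optional character vector of society identifiers that
#'   must be present among the tips.
#' @return an [ape::phylo] tree, with attribute `"unmatched_tips"` when
#'   `society_ids` was given.
#' @export
read_timetree <- function(path, society_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) NULL)
  if (is.null(tree)) stop("unparseable Newick in ", path, call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("tree in ", path, " has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("tree in ", path, " has negative branch length(s)", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicated tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (max(depths) > 0 && (max(depths) - min(depths)) / max(depths) > 0.01) {
    warning("root-to-tip depths vary by more than 1%; ",
            "tree is noticeably non-ultrametric", call. = FALSE)
  }
  if (!is.null(society_ids)) {
    missing <- setdiff(society_ids, tree$tip.label)
    if (length(missing)) {
      stop("society(ies) absent from the tree: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    unmatched <- setdiff(tree$tip.label, society_ids)
    if (length(unmatched)) {
      message(length(unmatched), " tip(s) without a matching society: ",
              paste(unmatched, collapse = ", "))
    }
    attr(tree, "unmatched_tips") <- unmatched
  }
  tree
}

#' Pairwise patristic time distances between societies
#'
#' The distance between two tips is the sum of branch lengths along the
#' unique path connecting them. On an ultrametric time tree this equals
#' twice the time to the most recent common ancestor; it remains
#' well-defined when the tree departs from ultrametricity.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param subset optional character vector of tip labels to restrict to.
#' @return a symmetric numeric matrix with zero diagonal, dimnames the
#'   society identifiers.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):4,C:5);")
#' patristic_distances(tr)  # d_AB = 2, d_AC = d_BC = 10
patristic_distances <- function(tree, subset = NULL) {
  d <- ape::cophenetic.phylo(tree)
  if (!is.null(subset)) {
    missing <- setdiff(subset, rownames(d))
    if (length(missing)) {
      stop("tip(s) not in tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    d <- d[subset, subset, drop = FALSE]
  }
  d
}

#' Phylogenetic-isolation resampling weights
#'
#' For each society in the analysis subsample, raw isolation is its mean
#' patristic time distance from every *other* society in that subsample;
#' weights are raw isolations normalized to sum to one. Weights must be
#' recomputed from scratch for each analysis subsample: the weights of a
#' subset are not, in general, the renormalized full-sample weights,
#' because every mean changes when societies leave the sample.
#'
#' @param dist square patristic distance matrix from
#'   [patristic_distances()].
#' @param subsample character vector of society identifiers to weight
#'   (default: all rows of `dist`); at least two.
#' @return a data.frame with columns `society_id`, `raw_isolation`,
#'   `weight` (weights sum to 1).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):4,C:5);")
#' isolation_weights(patristic_distances(tr))$weight  # 3/11, 3/11, 5/11
isolation_weights <- function(dist, subsample = NULL) {
  ids <- subsample %||% rownames(dist)
  if (length(ids) < 2) {
    stop("isolation weights require at least 2 societies", call. = FALSE)
  }
  missing <- setdiff(ids, rownames(dist))
  if (length(missing)) {
    stop("society(ies) not in distance matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- dist[ids, ids, drop = FALSE]
  m <- rowSums(d) / (length(ids) - 1)
  if (all(m == 0)) {
    stop("all pairwise distances are zero; isolation weights are undefined",
         call. = FALSE)
  }
  data.frame(
    society_id = ids,
    raw_isolation = unname(m),
    weight = unname(m / sum(m)),
    stringsAsFactors = FALSE
  )
}
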