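#' Affinity of a cross-class patient pair on a protein set
#'
#' Two patients of opposite response class have affinity 1 under a protein
#' set `K` when their binarized input values agree on every protein of `K`,
#' else 0.
#'
#' @param inputs binary matrix, patients x input proteins (rownames =
#'   patient ids).
#' @param K character vector of selected proteins (non-empty).
#' @param j,j2 patient ids (CR and PR member respectively).
#' @return 0 or 1.
#' @export
affinity <- function(inputs, K, j, j2) {
  if (length(K) == 0L) stop("K must be non-empty", call. = FALSE)
  missing <- setdiff(K, colnames(inputs))
  if (length(missing) > 0L) {
    stop("proteins absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as.integer(all(inputs[j, K] == inputs[j2, K]))
}

# all affinity pairs for one protein subset: tibble(cr_patient, pr_patient)
affinity_pairs <- function(inputs_cr, inputs_pr, K) {
  key_cr <- apply(inputs_cr[, K, drop = FALSE], 1L, paste, collapse = "")
  key_pr <- apply(inputs_pr[, K, drop = FALSE], 1L, paste, collapse = "")
  hits <- outer(key_cr, key_pr, `==`)
  idx <- which(hits, arr.ind = TRUE)
  tibble::tibble(cr_patient = rownames(inputs_cr)[idx[, 1L]],
                 pr_patient = rownames(inputs_pr)[idx[, 2L]])
}

#' Maximum set of non-redundant couples from affinity pairs
#'
#' A couple is redundant when it shares a patient with another couple; the
#' maximum number of pairwise non-redundant couples is the maximum-cardinality
#' matching of the bipartite affinity graph (CR patients vs PR patients).
#'
#' @param pairs tibble with columns `cr_patient`, `pr_patient`.
#' @param gap optional named weight per pair (e.g. readout divergence): among
#'   maximum matchings, one maximizing the total weight is returned.
#' @return tibble of couples (`cr_patient`, `pr_patient`), a maximum
#'   matching; attribute `gap` holds the total weight when `gap` was given.
#' @export
max_nonredundant_couples <- function(pairs, gap = NULL) {
  if (nrow(pairs) == 0L) {
    return(structure(tibble::tibble(cr_patient = character(),
                                    pr_patient = character()), gap = 0))
  }
  cr <- unique(pairs$cr_patient)
  pr <- unique(pairs$pr_patient)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, length(cr)), rep(TRUE, length(pr))),
    edges = rbind(match(pairs$cr_patient, cr),
                  length(cr) + match(pairs$pr_patient, pr))
  )
  igraph::V(g)$name <- c(cr, pr)
  if (is.null(gap)) {
    m <- igraph::max_bipartite_match(g)
  } else {
    # large constant keeps cardinality primary, weight secondary
    big <- sum(gap) + 1
    m <- igraph::max_bipartite_match(g, weights = big + gap, eps = 1e-9)
  }
  mate <- m$matching[cr]
  matched <- !is.na(mate)
  couples <- tibble::tibble(cr_patient = cr[matched],
                            pr_patient = unname(mate[matched]))
  couples <- couples[order(couples$cr_patient), ]
  total_gap <- if (is.null(gap)) 0 else {
    sum(gap[match(paste(couples$cr_patient, couples$pr_patient),
                  paste(pairs$cr_patient, pairs$pr_patient))])
  }
  structure(couples, gap = total_gap)
}

#' Total readout divergence over a set of couples
#'
#' Sum, over couples and readouts, of the absolute difference between the
#' CR member's and the PR member's normalized readout value.
#'
#' @param readouts_cr,readouts_pr normalized readout matrices with patient
#'   rownames.
#' @param couples tibble with `cr_patient`, `pr_patient`.
#' @return nonnegative scalar.
#' @export
readout_gap <- function(readouts_cr, readouts_pr, couples) {
  if (nrow(couples) == 0L) return(0)
  sum(abs(readouts_cr[couples$cr_patient, , drop = FALSE] -
            readouts_pr[couples$pr_patient, , drop = FALSE]))
}

# pairwise gap matrix between all CR and PR patients (rows CR, cols PR)
pairwise_gap <- function(readouts_cr, readouts_pr) {
  n_cr <- nrow(readouts_cr)
  n_pr <- nrow(readouts_pr)
  g <- matrix(0, n_cr, n_pr,
              dimnames = list(rownames(readouts_cr), rownames(readouts_pr)))
  for (r in seq_len(ncol(readouts_cr))) {
    g <- g + abs(outer(readouts_cr[, r], readouts_pr[, r], `-`))
  }
  g
}

#' Select the input-protein set maximizing non-redundant patient couples
#'
#' Scans every size-`k` subset of the binarized input proteins. For each
#' subset the CR x PR pairs with identical binarized profiles on the subset
#' (affinity pairs) are computed and the maximum number of non-redundant
#' couples (maximum bipartite matching) is taken as the primary objective.
#' When several subsets (or several maximum matchings) attain the optimum,
#' the total readout divergence over the chosen couples breaks the tie:
#' co-optimal selections are ranked by decreasing gap, then by protein names.
#'
#' @param proc a `processed_patients` object holding both classes.
#' @param k number of proteins to select.
#' @param strategy only `"exhaustive"` is implemented (the exact reference
#'   search over all subsets).
#' @return object of class `bn_selection_set`: list of selection results,
#'   best first; each has `proteins`, `couples` (tibble), `n_couples`,
#'   `affinity_count` (total affinity pairs), `n_redundant` (affinity pairs
#'   sharing a patient with another pair), `readout_gap`.
#' @export
select_proteins <- function(proc, k, strategy = "exhaustive") {
  strategy <- match.arg(strategy, "exhaustive")
  stopifnot(inherits(proc, "processed_patients"))
  split <- split_by_class(proc)
  inputs_cr <- split$CR$inputs
  inputs_pr <- split$PR$inputs
  prots <- colnames(inputs_cr)
  if (k > length(prots)) {
    stop("k = ", k, " exceeds the ", length(prots), " input proteins",
         call. = FALSE)
  }
  gapmat <- pairwise_gap(split$CR$readouts, split$PR$readouts)
  subsets <- utils::combn(prots, k, simplify = FALSE)

  best_n <- -1L
  cands <- list()
  for (K in subsets) {
    pairs <- affinity_pairs(inputs_cr, inputs_pr, K)
    if (nrow(pairs) < best_n) next  # cannot beat the best matching
    m <- max_nonredundant_couples(pairs)
    if (nrow(m) > best_n) {
      best_n <- nrow(m)
      cands <- list()
    }
    if (nrow(m) == best_n) cands[[length(cands) + 1L]] <- list(K = K,
                                                               pairs = pairs)
  }
  if (best_n == 0L) {
    warning("no affinity couple achievable for any subset", call. = FALSE)
    return(structure(list(), class = "bn_selection_set", k = k))
  }
  results <- lapply(cands, function(cd) {
    gap_w <- gapmat[cbind(cd$pairs$cr_patient, cd$pairs$pr_patient)]
    couples <- max_nonredundant_couples(cd$pairs, gap = gap_w)
    shared <- duplicated(cd$pairs$cr_patient) |
      duplicated(cd$pairs$cr_patient, fromLast = TRUE) |
      duplicated(cd$pairs$pr_patient) |
      duplicated(cd$pairs$pr_patient, fromLast = TRUE)
    structure(list(k = k,
                   proteins = sort(cd$K),
                   couples = tibble::as_tibble(couples),
                   n_couples = nrow(couples),
                   affinity_count = nrow(cd$pairs),
                   n_redundant = sum(shared),
                   readout_gap = attr(couples, "gap")),
              class = "bn_selection")
  })
  ord <- order(-vapply(results, `[[`, numeric(1), "readout_gap"),
               vapply(results, function(r) paste(r$proteins, collapse = ","),
                      character(1)))
  structure(results[ord], class = "bn_selection_set", k = k)
}

#' @export
print.bn_selection <- function(x, ...) {
  cat("<bn_selection> k = ", x$k, ": {", paste(x$proteins, collapse = ", "),
      "}; ", x$n_couples, " non-redundant couples (",
      x$affinity_count, " affinity pairs, ", x$n_redundant,
      " redundant), readout gap ", format(x$readout_gap, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.bn_selection_set <- function(x, ...) {
  cat("<bn_selection_set> ", length(x), " co-optimal selection(s) for k = ",
      attr(x, "k"), "\n", sep = "")
  if (length(x) > 0L) print(x[[1L]])
  invisible(x)
}

#' @export
tidy.bn_selection <- function(x, ...) x$couples

#' @export
glance.bn_selection <- function(x, ...) {
  tibble::tibble(k = x$k, n_couples = x$n_couples,
                 affinity_count = x$affinity_count,
                 n_redundant = x$n_redundant, readout_gap = x$readout_gap,
                 proteins = paste(x$proteins, collapse = ","))
}

#' Sweep the selection over a range of k
#'
#' Runs [select_proteins()] for each `k` and reports, at each optimum, the
#' number of non-redundant couples, the number of redundant affinity pairs,
#' the total affinity-pair count and the readout gap. Used to choose `k` as
#' the best compromise between couple count and redundancy.
#'
#' @param proc a `processed_patients` object.
#' @param k_range integer vector of subset sizes.
#' @return tibble (class `bn_k_sweep`) with one row per k.
#' @export
sweep_k <- function(proc, k_range) {
  rows <- lapply(k_range, function(k) {
    sel <- select_proteins(proc, k)
    if (length(sel) == 0L) {
      tibble::tibble(k = k, n_couples = 0L, n_redundant = 0L,
                     affinity_count = 0L, readout_gap = 0,
                     proteins = NA_character_)
    } else {
      glance(sel[[1L]])[, c("k", "n_couples", "n_redundant",
                            "affinity_count", "readout_gap", "proteins")]
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bn_k_sweep", class(out))
  out
}

#' Build the two reduced class datasets from a selection
#'
#' One experiment per couple: both classes carry the couple's shared
#' binarized input profile on the selected proteins (taken from the CR
#' member; by construction it equals the PR member's) and the
#' class-appropriate member's normalized readouts, row-aligned across
#' classes.
#'
#' @param proc a `processed_patients` object.
#' @param sel a `bn_selection` (or a `bn_selection_set`: its best element).
#' @return named list `CR` / `PR` of [experiments()] objects.
#' @export
build_reduced_datasets <- function(proc, sel) {
  if (inherits(sel, "bn_selection_set")) {
    if (length(sel) == 0L) stop("empty selection set", call. = FALSE)
    sel <- sel[[1L]]
  }
  stopifnot(inherits(sel, "bn_selection"))
  if (nrow(sel$couples) == 0L) stop("selection has no couples", call. = FALSE)
  shared <- proc$inputs[sel$couples$cr_patient, sel$proteins, drop = FALSE]
  rownames(shared) <- NULL
  mk <- function(pats) {
    obs <- proc$readouts[pats, , drop = FALSE]
    rownames(obs) <- NULL
    experiments(shared, obs)
  }
  list(CR = mk(sel$couples$cr_patient), PR = mk(sel$couples$pr_patient))
}
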