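#' Construct a Boolean network as a clause subset of a hypergraph
#'
#' A Boolean network is a subset of the candidate AND-clause catalogue of a
#' hypergraph; clauses sharing a target are OR-ed, so each node carries an
#' OR-of-ANDs update rule over its selected clauses.
#'
#' @param hg a `bn_hypergraph` from [expand_hypergraph()].
#' @param clause_ids integer ids (rows of `hg$clauses$id`) selected.
#' @return object of class `boolean_network`.
#' @export
boolean_network <- function(hg, clause_ids) {
  stopifnot(inherits(hg, "bn_hypergraph"))
  clause_ids <- sort(unique(as.integer(clause_ids)))
  if (!all(clause_ids %in% hg$clauses$id)) {
    stop("clause ids outside the hypergraph catalogue", call. = FALSE)
  }
  structure(list(hypergraph = hg, clauses = clause_ids),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("<boolean_network> ", length(x$clauses), " clauses\n", sep = "")
  lab <- x$hypergraph$clauses$label[match(x$clauses, x$hypergraph$clauses$id)]
  for (l in lab) cat("  ", l, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.boolean_network <- function(x, ...) {
  x$hypergraph$clauses[match(x$clauses, x$hypergraph$clauses$id), ]
}

# ---- synchronous fixpoint engine ------------------------------------------
#
# Evaluates many (clause-subset, experiment) pairs at once. States for all
# pairs are stacked as rows of one logical matrix and updated synchronously:
# clause activity is computed by columnwise literal tests, masked by each
# row's clause subset, and OR-aggregated per target through an incidence
# matrix product. Unclamped nodes start at 0; clamped nodes are held fixed.
# Rows not converged after |nodes| + 1 sweeps are flagged oscillatory.
#
# cand:    tibble of candidate clauses (target, source1, sign1, source2, sign2)
# submask: S x nrow(cand) logical, one row per clause subset
# clamp:   E x k 0/1 matrix, colnames = clamped node ids
# returns list(state = (S*E) x N logical [readouts of oscillatory rows
# zeroed], oscillatory = logical S*E); row order is subset-major
# ((s-1)*E + e).
bn_engine <- function(pkn_nodes_all, cand, submask, clamp, warn_oscillation = TRUE) {
  nodes <- pkn_nodes_all
  N <- length(nodes)
  C <- nrow(cand)
  S <- nrow(submask)
  E <- nrow(clamp)
  R <- S * E
  clamp_nodes <- colnames(clamp)
  stopifnot(all(clamp_nodes %in% nodes))
  clamp_idx <- match(clamp_nodes, nodes)

  clamp_full <- matrix(as.logical(clamp[rep(seq_len(E), times = S), ,
                                        drop = FALSE]),
                       nrow = R)
  mask_full <- submask[rep(seq_len(S), each = E), , drop = FALSE]

  state <- matrix(FALSE, nrow = R, ncol = N)
  state[, clamp_idx] <- clamp_full

  if (C == 0L) {
    return(list(state = state, oscillatory = rep(FALSE, R), nodes = nodes))
  }

  l1 <- match(cand$source1, nodes)
  neg1 <- cand$sign1 < 0
  has2 <- !is.na(cand$source2)
  l2 <- ifelse(has2, match(cand$source2, nodes), l1)
  neg2 <- ifelse(has2, cand$sign2 < 0, FALSE)
  # clause -> target incidence
  inc <- matrix(0L, nrow = C, ncol = N)
  inc[cbind(seq_len(C), match(cand$target, nodes))] <- 1L

  step <- function(st) {
    a <- st[, l1, drop = FALSE]
    if (any(neg1)) a[, neg1] <- !a[, neg1, drop = FALSE]
    b <- st[, l2, drop = FALSE]
    if (any(neg2)) b[, neg2] <- !b[, neg2, drop = FALSE]
    if (any(!has2)) b[, !has2] <- TRUE
    cv <- a & b & mask_full
    nst <- (cv %*% inc) > 0
    nst[, clamp_idx] <- clamp_full
    nst
  }

  cap <- N + 1L
  iter <- 0L
  repeat {
    nst <- step(state)
    if (iter >= cap) break
    if (identical(nst, state)) break
    state <- nst
    iter <- iter + 1L
  }
  oscillatory <- rowSums(nst != state) > 0L
  if (any(oscillatory)) {
    if (warn_oscillation) {
      warning(sum(oscillatory),
              " run(s) did not reach a fixed point; their readouts are 0",
              call. = FALSE)
    }
    # non-converged rows: all non-clamped values (hence readouts) report 0
    unclamped <- setdiff(seq_len(N), clamp_idx)
    state[oscillatory, unclamped] <- FALSE
  }
  list(state = state, oscillatory = oscillatory, nodes = nodes)
}

#' Logical steady state of a Boolean network under clamped inputs
#'
#' Clamped nodes are held at their given value; every other node starts at 0
#' and is updated synchronously by the OR of its selected AND clauses until a
#' fixed point, with an iteration cap of `|nodes| + 1`. If the trajectory has
#' not stabilized at the cap the run is oscillatory: unclamped nodes
#' (including the readouts) report 0 and a warning is raised.
#'
#' @param net a [boolean_network()].
#' @param clamped named 0/1 vector of clamped node values.
#' @param inputs node ids that must be clamped (default: the names of
#'   `clamped`); a missing clamp is an error.
#' @return named integer 0/1 vector over all PKN nodes.
#' @export
fixpoint <- function(net, clamped, inputs = names(clamped)) {
  stopifnot(inherits(net, "boolean_network"))
  if (is.null(names(clamped)) || !all(nzchar(names(clamped)))) {
    stop("`clamped` must be a named vector", call. = FALSE)
  }
  missing <- setdiff(inputs, names(clamped))
  if (length(missing) > 0L) {
    stop("missing clamp for input node(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hg <- net$hypergraph
  cand <- hg$clauses[match(net$clauses, hg$clauses$id), , drop = FALSE]
  clamp <- matrix(as.integer(clamped), nrow = 1L,
                  dimnames = list(NULL, names(clamped)))
  res <- bn_engine(hg$pkn$nodes, cand,
                   submask = matrix(TRUE, 1L, nrow(cand)), clamp = clamp)
  stats::setNames(as.integer(res$state[1L, ]), res$nodes)
}

# ---- experiments -----------------------------------------------------------

#' Bundle perturbation experiments for network learning
#'
#' Each experiment clamps the selected input proteins to a 0/1 profile and
#' observes normalized readout values in \[0,1\].
#'
#' @param clamped E x k 0/1 matrix, colnames = clamped node ids.
#' @param observed E x r numeric matrix in \[0,1\], colnames = readout ids.
#' @return object of class `bn_experiments`.
#' @export
experiments <- function(clamped, observed) {
  clamped <- as.matrix(clamped)
  observed <- as.matrix(observed)
  stopifnot(nrow(clamped) == nrow(observed),
            !is.null(colnames(clamped)), !is.null(colnames(observed)),
            all(clamped %in% c(0, 1)),
            all(observed >= 0 & observed <= 1))
  storage.mode(clamped) <- "integer"
  structure(list(clamped = clamped, observed = observed),
            class = "bn_experiments")
}

#' @export
print.bn_experiments <- function(x, ...) {
  cat("<bn_experiments> ", nrow(x$clamped), " experiments, ",
      ncol(x$clamped), " clamped inputs, ", ncol(x$observed),
      " observed readouts\n", sep = "")
  invisible(x)
}

#' One experiment per patient from a processed dataset
#'
#' @param proc a `processed_patients` object.
#' @param input_proteins which binarized columns to clamp (default all).
#' @return a [experiments()] object.
#' @export
experiments_from_patients <- function(proc,
                                      input_proteins = colnames(proc$inputs)) {
  stopifnot(inherits(proc, "processed_patients"))
  experiments(proc$inputs[, input_proteins, drop = FALSE], proc$readouts)
}

# ---- learning --------------------------------------------------------------

#' Learn the family of co-optimal Boolean networks
#'
#' Scores every subset of the candidate clause catalogue against the
#' experiments and returns all subsets that are optimal under the
#' lexicographic objective: minimal mean squared error between predicted and
#' observed readouts first, minimal size (number of selected clauses) among
#' those second. Tolerances relax each stage: a subset is kept when its MSE
#' is within `fit_tolerance` of the global minimum and its size within
#' `size_tolerance` of the smallest size among MSE-optimal subsets.
#'
#' Clauses whose target is clamped in the experiments cannot influence any
#' prediction (the clamp overrides the update rule) and are removed from the
#' search space before enumeration.
#'
#' @param hg a `bn_hypergraph`.
#' @param exps a [experiments()] object.
#' @param fit_tolerance nonnegative MSE slack (default 0: strict co-optima).
#' @param size_tolerance nonnegative integer size slack (default 0).
#' @param exhaustive_cap refuse to enumerate more than `2^exhaustive_cap`
#'   subsets (default 20).
#' @param chunk_size subsets scored per vectorized block.
#' @return object of class `bn_family`: list with `networks` (list of clause
#'   id vectors), `mse` and `size` of the optimum, `inputs`, `readouts`,
#'   `hypergraph`, and `behaviors` (filled by [classify_behaviors()]).
#' @export
learn_networks <- function(hg, exps, fit_tolerance = 0, size_tolerance = 0,
                           exhaustive_cap = 20, chunk_size = 2048L) {
  stopifnot(inherits(hg, "bn_hypergraph"), inherits(exps, "bn_experiments"),
            fit_tolerance >= 0, size_tolerance >= 0)
  if (nrow(exps$clamped) == 0L) stop("no experiments", call. = FALSE)
  clamp_nodes <- colnames(exps$clamped)
  readouts <- colnames(exps$observed)
  if (!all(readouts %in% hg$pkn$nodes)) {
    stop("observed readouts absent from the PKN: ",
         paste(setdiff(readouts, hg$pkn$nodes), collapse = ", "),
         call. = FALSE)
  }
  cand <- hg$clauses[!(hg$clauses$target %in% clamp_nodes), , drop = FALSE]
  n <- nrow(cand)
  if (n > exhaustive_cap) {
    stop("candidate clause catalogue has ", n, " clauses (> cap ",
         exhaustive_cap, "): exhaustive enumeration of 2^", n,
         " networks refused; reduce the hypergraph or raise `exhaustive_cap`",
         call. = FALSE)
  }
  n_subsets <- 2^n
  obs <- exps$observed
  E <- nrow(obs)
  r_idx <- match(readouts, hg$pkn$nodes)

  mse_all <- numeric(n_subsets)
  size_all <- integer(n_subsets)
  start <- 0
  while (start < n_subsets) {
    idx <- start:min(start + chunk_size - 1, n_subsets - 1)
    S <- length(idx)
    submask <- matrix(FALSE, S, max(n, 1L))
    for (b in seq_len(n)) submask[, b] <- bitwAnd(idx, 2^(b - 1)) > 0
    if (n == 0L) submask <- matrix(FALSE, S, 0L)
    res <- bn_engine(hg$pkn$nodes, cand, submask, exps$clamped,
                     warn_oscillation = FALSE)
    pred <- res$state[, r_idx, drop = FALSE] * 1
    err2 <- (pred - obs[rep(seq_len(E), times = S), , drop = FALSE])^2
    mse_all[idx + 1] <- rowsum(rowSums(err2), rep(seq_len(S), each = E),
                               reorder = FALSE) / (E * ncol(obs))
    size_all[idx + 1] <- rowSums(submask)
    start <- start + chunk_size
  }

  min_mse <- min(mse_all)
  fit_ok <- mse_all <= min_mse + fit_tolerance
  min_size <- min(size_all[fit_ok])
  keep <- which(fit_ok & size_all <= min_size + size_tolerance)
  networks <- lapply(keep - 1, function(code) {
    cand$id[bitwAnd(code, 2^(seq_len(n) - 1)) > 0]
  })
  structure(list(hypergraph = hg, networks = networks,
                 mse = min_mse, size = min_size,
                 mse_per_network = mse_all[keep],
                 size_per_network = size_all[keep],
                 inputs = clamp_nodes, readouts = readouts,
                 behaviors = NULL),
            class = "bn_family")
}

#' @export
print.bn_family <- function(x, ...) {
  cat("<bn_family> ", length(x$networks), " co-optimal networks (MSE ",
      format(x$mse, digits = 4), ", size ", x$size, ")",
      if (!is.null(x$behaviors)) paste0(", ",
                                        length(unique(x$behaviors)),
                                        " I/O behaviors"),
      "\n", sep = "")
  invisible(x)
}

#' @export
glance.bn_family <- function(x, ...) {
  tibble::tibble(
    n_networks = length(x$networks),
    mse = x$mse,
    size = x$size,
    n_behaviors = if (is.null(x$behaviors)) NA_integer_ else
      length(unique(x$behaviors)),
    search_space_log2 = nrow(x$hypergraph$clauses)
  )
}

#' @export
tidy.bn_family <- function(x, ...) clause_frequencies(x)

# readout predictions of each network in a family for a clamp matrix:
# returns array nets x E x readouts collapsed as a list of matrices helper
family_predictions <- function(family, clamp, readouts) {
  hg <- family$hypergraph
  ids <- hg$clauses$id
  # candidate set = union of family clauses (others never selected)
  used <- sort(unique(unlist(family$networks)))
  cand <- hg$clauses[match(used, ids), , drop = FALSE]
  submask <- do.call(rbind, lapply(family$networks,
                                   function(cl) used %in% cl))
  if (length(family$networks) == 1L) submask <- matrix(submask, nrow = 1L)
  if (length(used) == 0L) {
    submask <- matrix(FALSE, length(family$networks), 0L)
  }
  res <- bn_engine(hg$pkn$nodes, cand, submask, clamp,
                   warn_oscillation = FALSE)
  r_idx <- match(readouts, hg$pkn$nodes)
  E <- nrow(clamp)
  lapply(seq_along(family$networks), function(s) {
    rows <- (s - 1L) * E + seq_len(E)
    m <- res$state[rows, r_idx, drop = FALSE] * 1
    colnames(m) <- readouts
    m
  })
}

#' Predict readout values from a network or family
#'
#' For a family the prediction is the per-readout mean of the member
#' networks' logical steady states (`aggregate = "networks"`, default) or the
#' mean over one representative of each input-output behavior group
#' (`aggregate = "behaviors"`, requires [classify_behaviors()] first).
#'
#' @param object a `bn_family` or `boolean_network`.
#' @param clamped named 0/1 vector (or E x k matrix) of clamped inputs.
#' @param readouts readout node ids (default: the family's readouts).
#' @param aggregate `"networks"` or `"behaviors"`.
#' @param ... unused.
#' @return named numeric vector in \[0,1\] (or E x r matrix when `clamped`
#'   is a matrix).
#' @export
predict.bn_family <- function(object, clamped, readouts = object$readouts,
                              aggregate = c("networks", "behaviors"), ...) {
  aggregate <- match.arg(aggregate)
  if (length(object$networks) == 0L) stop("empty family", call. = FALSE)
  vec_in <- is.null(dim(clamped))
  clamp <- if (vec_in) {
    matrix(as.integer(clamped), nrow = 1L,
           dimnames = list(NULL, names(clamped)))
  } else as.matrix(clamped)
  preds <- family_predictions(object, clamp, readouts)
  if (aggregate == "behaviors") {
    if (is.null(object$behaviors)) {
      stop("run classify_behaviors() before aggregate = \"behaviors\"",
           call. = FALSE)
    }
    reps <- match(unique(object$behaviors), object$behaviors)
    preds <- preds[reps]
  }
  out <- Reduce(`+`, preds) / length(preds)
  if (vec_in) stats::setNames(out[1L, ], colnames(out)) else out
}

#' @export
predict.boolean_network <- function(object, clamped,
                                    readouts = NULL, ...) {
  fp <- fixpoint(object, clamped)
  if (is.null(readouts)) fp else fp[readouts]
}

#' Mean squared error of predictions against experiments
#'
#' Mean over all (experiment, readout) cells of the squared difference
#' between the predicted and observed readout value.
#'
#' @param object a `bn_family` or `boolean_network`.
#' @param exps a [experiments()] object.
#' @param readouts readout ids (default: the observed columns).
#' @param ... passed to [predict.bn_family()] (e.g. `aggregate`).
#' @return nonnegative scalar (at most 1, both operands live in \[0,1\]).
#' @export
mse <- function(object, exps, readouts = colnames(exps$observed), ...) {
  stopifnot(inherits(exps, "bn_experiments"))
  if (nrow(exps$clamped) == 0L) stop("no experiments", call. = FALSE)
  pred <- if (inherits(object, "bn_family")) {
    predict(object, exps$clamped, readouts = readouts, ...)
  } else {
    do.call(rbind, lapply(seq_len(nrow(exps$clamped)), function(e) {
      fixpoint(object, exps$clamped[e, ])[readouts]
    }))
  }
  mean((pred - exps$observed[, readouts, drop = FALSE])^2)
}

#' Group a family's networks by input-output behavior
#'
#' Two networks share a behavior when their readout steady states coincide
#' for every one of the `2^n` clampings of the `n` input nodes.
#'
#' @param family a `bn_family`.
#' @param input_nodes clamped input ids (default: the family's inputs);
#'   at most 20 (full clamping enumeration).
#' @param readouts readout ids (default: the family's readouts).
#' @return the family with `behaviors` set: integer group id per network
#'   (group 1 = first network's behavior, in enumeration order).
#' @export
classify_behaviors <- function(family, input_nodes = family$inputs,
                               readouts = family$readouts) {
  stopifnot(inherits(family, "bn_family"))
  n <- length(input_nodes)
  if (n > 20) {
    stop("behavior classification enumerates 2^n clampings; ", n,
         " inputs is too many (max 20)", call. = FALSE)
  }
  clamp <- all_clampings(input_nodes)
  preds <- family_predictions(family, clamp, readouts)
  sig <- vapply(preds, function(m) paste(m, collapse = ","), character(1))
  family$behaviors <- match(sig, unique(sig))
  family
}

# all 2^n 0/1 clamping profiles of the given nodes, deterministic order
all_clampings <- function(input_nodes) {
  n <- length(input_nodes)
  idx <- 0:(2^n - 1)
  m <- vapply(seq_len(n), function(b) as.integer(bitwAnd(idx, 2^(b - 1)) > 0),
              integer(length(idx)))
  if (length(idx) == 1L) m <- matrix(m, nrow = 1L)
  colnames(m) <- input_nodes
  m
}

#' Frequency of each clause across a family
#'
#' The frequency of a clause is the fraction of member networks containing
#' it; clauses absent from every network are omitted.
#'
#' @param family a `bn_family`.
#' @return tibble with columns `id`, `target`, `label`, `frequency`, sorted
#'   by decreasing frequency.
#' @export
clause_frequencies <- function(family) {
  stopifnot(inherits(family, "bn_family"))
  if (length(family$networks) == 0L) stop("empty family", call. = FALSE)
  counts <- table(unlist(family$networks))
  ids <- as.integer(names(counts))
  cl <- family$hypergraph$clauses
  out <- tibble::tibble(
    id = ids,
    target = cl$target[match(ids, cl$id)],
    label = cl$label[match(ids, cl$id)],
    frequency = as.numeric(counts) / length(family$networks)
  )
  dplyr::arrange(out, dplyr::desc(.data$frequency), .data$id)
}

#' Union network of a family
#'
#' The clause-set union across all member networks, annotated with each
#' clause's family frequency (the analog of the thick edges in family-union
#' diagrams). The union is a reporting device: it carries no optimality
#' guarantee of its own.
#'
#' @param family a `bn_family`.
#' @return a [boolean_network()] with attribute `frequencies` (the
#'   [clause_frequencies()] tibble).
#' @export
union_network <- function(family) {
  stopifnot(inherits(family, "bn_family"))
  if (length(family$networks) == 0L) stop("empty family", call. = FALSE)
  net <- boolean_network(family$hypergraph,
                         sort(unique(unlist(family$networks))))
  attr(net, "frequencies") <- clause_frequencies(family)
  net
}

# ---- serialization ---------------------------------------------------------

#' Serialize a network or family to JSON
#'
#' Networks are written as lists of clauses (`target`, `literals` with
#' `node`/`sign`) so they can be exchanged without the hypergraph object.
#'
#' @param x a `boolean_network` or `bn_family`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(x, path) {
  clause_list <- function(ids, hg) {
    cl <- hg$clauses[match(ids, hg$clauses$id), , drop = FALSE]
    lapply(seq_len(nrow(cl)), function(i) {
      lits <- list(list(node = cl$source1[i], sign = cl$sign1[i]))
      if (!is.na(cl$source2[i])) {
        lits[[2]] <- list(node = cl$source2[i], sign = cl$sign2[i])
      }
      list(target = cl$target[i], literals = lits)
    })
  }
  obj <- if (inherits(x, "boolean_network")) {
    list(type = "network", clauses = clause_list(x$clauses, x$hypergraph))
  } else if (inherits(x, "bn_family")) {
    list(type = "family", mse = x$mse, size = x$size,
         behaviors = x$behaviors,
         networks = lapply(x$networks, clause_list, hg = x$hypergraph))
  } else stop("unsupported object", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a network as an extended SIF with AND-gate pseudo-nodes
#'
#' Single-literal clauses become ordinary signed edges; a two-literal clause
#' becomes two signed edges into an `AND:<target>:<i>` pseudo-node plus a
#' positive edge from the pseudo-node to the target.
#'
#' @param net a `boolean_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(net, path) {
  stopifnot(inherits(net, "boolean_network"))
  cl <- tidy(net)
  lines <- character(0)
  and_i <- 0L
  for (i in seq_len(nrow(cl))) {
    if (is.na(cl$source2[i])) {
      lines <- c(lines, paste(cl$source1[i], cl$sign1[i], cl$target[i],
                              sep = "\t"))
    } else {
      and_i <- and_i + 1L
      gate <- paste0("AND:", cl$target[i], ":", and_i)
      lines <- c(lines,
                 paste(cl$source1[i], cl$sign1[i], gate, sep = "\t"),
                 paste(cl$source2[i], cl$sign2[i], gate, sep = "\t"),
                 paste(gate, 1L, cl$target[i], sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
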