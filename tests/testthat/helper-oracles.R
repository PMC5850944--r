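# Independent oracles used to cross-check the package's optimized routines.
# Each oracle is written as plain enumeration / recursion over a small
# instance and deliberately shares no code with the implementation it checks.

# --- synchronous Boolean simulation ------------------------------------------
# Step-by-step synchronous update with explicit per-clause evaluation, same
# contract as fixpoint(): unclamped nodes start at 0, clamped nodes held,
# iteration horizon |nodes| + 1, non-convergence zeroes unclamped nodes.
oracle_sync <- function(nodes, clauses, clamped) {
  state <- stats::setNames(rep(0L, length(nodes)), nodes)
  state[names(clamped)] <- as.integer(clamped)
  unclamped <- setdiff(nodes, names(clamped))
  for (step in seq_len(length(nodes) + 2L)) {
    new <- stats::setNames(rep(0L, length(nodes)), nodes)
    if (nrow(clauses) > 0L) {
      for (i in seq_len(nrow(clauses))) {
        v1 <- state[[clauses$source1[i]]]
        if (clauses$sign1[i] < 0) v1 <- 1L - v1
        v2 <- 1L
        if (!is.na(clauses$source2[i])) {
          v2 <- state[[clauses$source2[i]]]
          if (clauses$sign2[i] < 0) v2 <- 1L - v2
        }
        if (v1 == 1L && v2 == 1L) new[[clauses$target[i]]] <- 1L
      }
    }
    new[names(clamped)] <- as.integer(clamped)
    if (all(new == state)) return(list(state = state, converged = TRUE))
    if (step > length(nodes) + 1L) break
    state <- new
  }
  state[unclamped] <- 0L
  list(state = state, converged = FALSE)
}

# score one clause subset against experiments by oracle simulation
oracle_mse <- function(nodes, clauses, clamp, observed) {
  total <- 0
  for (e in seq_len(nrow(clamp))) {
    st <- oracle_sync(nodes, clauses, clamp[e, ])$state
    total <- total + sum((st[colnames(observed)] - observed[e, ])^2)
  }
  total / (nrow(observed) * ncol(observed))
}

# enumerate every subset of the candidate clauses, return all co-optimal
# (min MSE, then min size) subsets as a list of sorted id vectors
oracle_learn <- function(nodes, cand, clamp, observed, tol = 1e-12) {
  n <- nrow(cand)
  scores <- vapply(0:(2^n - 1), function(code) {
    sel <- bitwAnd(code, 2^(seq_len(n) - 1)) > 0
    oracle_mse(nodes, cand[sel, , drop = FALSE], clamp, observed)
  }, numeric(1))
  sizes <- vapply(0:(2^n - 1), function(code) {
    sum(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
  }, numeric(1))
  fit_ok <- scores <= min(scores) + tol
  min_size <- min(sizes[fit_ok])
  keep <- which(fit_ok & sizes == min_size) - 1
  list(mse = min(scores), size = min_size,
       subsets = lapply(keep, function(code) {
         sort(cand$id[bitwAnd(code, 2^(seq_len(n) - 1)) > 0])
       }))
}

# --- bipartite matching ------------------------------------------------------
# exact maximum-cardinality, then maximum-gap matching by recursion over CR
# patients with a PR usage bitmask (lexicographic objective)
oracle_matching <- function(pairs, gapmat = NULL) {
  cr <- sort(unique(pairs$cr_patient))
  pr <- sort(unique(pairs$pr_patient))
  adj <- lapply(cr, function(c) which(pr %in% pairs$pr_patient[
    pairs$cr_patient == c]))
  memo <- new.env(parent = emptyenv())
  rec <- function(i, used) {
    if (i > length(cr)) return(c(0, 0))
    key <- paste(i, used)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, used)  # skip this CR patient
    for (p in adj[[i]]) {
      if (bitwAnd(used, bitwShiftL(1L, p - 1L)) == 0L) {
        g <- if (is.null(gapmat)) 0 else gapmat[cr[i], pr[p]]
        cand <- rec(i + 1L, bitwOr(used, bitwShiftL(1L, p - 1L))) + c(1, g)
        if (cand[1] > best[1] ||
            (cand[1] == best[1] && cand[2] > best[2] + 1e-12)) best <- cand
      }
    }
    memo[[key]] <- best
    best
  }
  res <- rec(1L, 0L)
  list(size = res[1], gap = res[2])
}

# brute-force protein-set selection: best (couples, gap) over all k-subsets
oracle_select <- function(inputs_cr, inputs_pr, gapmat, k) {
  prots <- colnames(inputs_cr)
  best <- list(size = -1, gap = -Inf)
  for (K in utils::combn(prots, k, simplify = FALSE)) {
    key_cr <- apply(inputs_cr[, K, drop = FALSE], 1, paste, collapse = "")
    key_pr <- apply(inputs_pr[, K, drop = FALSE], 1, paste, collapse = "")
    hit <- which(outer(key_cr, key_pr, `==`), arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    pairs <- data.frame(cr_patient = rownames(inputs_cr)[hit[, 1]],
                        pr_patient = rownames(inputs_pr)[hit[, 2]])
    m <- oracle_matching(pairs, gapmat)
    if (m$size > best$size ||
        (m$size == best$size && m$gap > best$gap + 1e-9)) best <- m
  }
  best
}

# --- misc --------------------------------------------------------------------
# brute-force 1-D 2-means: try every 2-labelling, return minimal
# within-cluster sum of squares
oracle_two_means_wss <- function(v) {
  n <- length(v)
  best <- Inf
  for (code in 1:(2^n - 2)) {
    lab <- bitwAnd(code, 2^(seq_len(n) - 1)) > 0
    wss <- sum((v[lab] - mean(v[lab]))^2) +
      sum((v[!lab] - mean(v[!lab]))^2)
    best <- min(best, wss)
  }
  best
}

# random processed dataset for selection tests (dyadic readouts keep MSE and
# gap arithmetic exact across summation orders)
random_proc <- function(n_cr, n_pr, n_prot, n_readout = 2) {
  inputs <- matrix(rbinom((n_cr + n_pr) * n_prot, 1, 0.5),
                   ncol = n_prot,
                   dimnames = list(c(sprintf("c%02d", seq_len(n_cr)),
                                     sprintf("p%02d", seq_len(n_pr))),
                                   sprintf("X%02d", seq_len(n_prot))))
  readouts <- matrix(sample(seq(0, 1, by = 0.25),
                            (n_cr + n_pr) * n_readout, replace = TRUE),
                     ncol = n_readout,
                     dimnames = list(rownames(inputs),
                                     sprintf("R%02d", seq_len(n_readout))))
  bnstrat:::new_processed_patients(
    inputs, readouts,
    stats::setNames(rep(c("CR", "PR"), c(n_cr, n_pr)), rownames(inputs)))
}

# random signed PKN whose hypergraph has at most `max_clauses` candidate
# clauses on unclamped targets; returns pkn, clamped input nodes, readouts
random_learn_instance <- function(max_clauses = 10, n_exp = 6) {
  repeat {
    n_sti <- sample(1:2, 1)
    n_mid <- sample(1:2, 1)
    n_rdo <- sample(1:2, 1)
    sti <- sprintf("s%d", seq_len(n_sti))
    mid <- sprintf("m%d", seq_len(n_mid))
    rdo <- sprintf("r%d", seq_len(n_rdo))
    ed <- list()
    for (m in mid) {
      src <- sample(sti, sample(1:min(2, n_sti), 1))
      ed[[length(ed) + 1]] <- data.frame(
        source = src, sign = sample(c(1, -1), length(src), TRUE), target = m)
    }
    for (r in rdo) {
      src <- sample(c(sti, mid), sample(1:2, 1))
      ed[[length(ed) + 1]] <- data.frame(
        source = src, sign = sample(c(1, -1), length(src), TRUE), target = r)
    }
    ed <- do.call(rbind, ed)
    ed <- ed[!duplicated(paste(ed$source, ed$sign, ed$target)), ]
    net <- suppressWarnings(pkn(ed))
    hg <- expand_hypergraph(net)
    clamped_nodes <- pkn_nodes(net, "stimulus")
    cand <- hg$clauses[!(hg$clauses$target %in% clamped_nodes), ]
    if (nrow(cand) >= 2 && nrow(cand) <= max_clauses) {
      clamp <- matrix(rbinom(n_exp * length(clamped_nodes), 1, 0.5),
                      nrow = n_exp,
                      dimnames = list(NULL, clamped_nodes))
      observed <- matrix(sample(seq(0, 1, 0.25), n_exp * n_rdo, TRUE),
                         nrow = n_exp, dimnames = list(NULL, rdo))
      return(list(pkn = net, hg = hg, cand = cand,
                  exps = experiments(clamp, observed)))
    }
  }
}
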