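# small fixed hypergraph: S (stimulus) and I (inhibitor input) regulate R
gate_hg <- function() {
  net <- suppressWarnings(pkn(data.frame(source = c("S", "I"),
                                         sign = c(1, -1), target = "R")))
  expand_hypergraph(net)
}

test_that("fixpoint evaluates AND gates under clamping", {
  hg <- gate_hg()
  and_id <- hg$clauses$id[!is.na(hg$clauses$source2)]  # R <- !I & S
  net <- boolean_network(hg, and_id)
  expect_equal(fixpoint(net, c(S = 1, I = 0))[["R"]], 1L)
  expect_equal(fixpoint(net, c(S = 1, I = 1))[["R"]], 0L)
  expect_equal(fixpoint(net, c(S = 0, I = 0))[["R"]], 0L)
  expect_error(fixpoint(net, c(S = 1), inputs = c("S", "I")), "missing clamp")
})

test_that("signals propagate through chains and match the step oracle", {
  chain <- pkn(data.frame(source = c("S", "A"), sign = 1,
                          target = c("A", "R")))
  hg <- expand_hypergraph(chain)
  net <- boolean_network(hg, hg$clauses$id)
  fp <- fixpoint(net, c(S = 1))
  expect_equal(unname(fp[c("A", "R")]), c(1L, 1L))
  oracle <- oracle_sync(chain$nodes, tidy(net), c(S = 1))
  expect_equal(fp, oracle$state)
})

test_that("oscillatory networks report zero readouts with a warning", {
  # negative 2-cycle feeding a readout: no fixed point from the zero state
  cyc <- suppressWarnings(pkn(data.frame(source = c("A", "B", "B"),
                                         sign = c(-1, -1, 1),
                                         target = c("B", "A", "R"))))
  hg <- expand_hypergraph(cyc)
  singles <- hg$clauses$id[is.na(hg$clauses$source2)]
  net <- boolean_network(hg, singles)
  expect_warning(fp <- fixpoint(net, stats::setNames(integer(0),
                                                     character(0))),
                 "fixed point")
  expect_equal(fp[["R"]], 0L)
  oracle <- oracle_sync(cyc$nodes, tidy(net), stats::setNames(integer(0),
                                                              character(0)))
  expect_false(oracle$converged)
})

test_that("learning recovers the single consistent clause", {
  hg <- gate_hg()
  # catalogue restricted to R <- S / R <- !S via a two-edge PKN on one source
  net2 <- pkn(data.frame(source = "S", sign = c(1, -1), target = "R"))
  hg2 <- expand_hypergraph(net2)
  exps <- experiments(matrix(c(1L, 0L), 2, dimnames = list(NULL, "S")),
                      matrix(c(1, 0), 2, dimnames = list(NULL, "R")))
  fam <- learn_networks(hg2, exps)
  expect_equal(length(fam$networks), 1)
  expect_equal(fam$mse, 0)
  expect_equal(fam$size, 1)
  expect_equal(hg2$clauses$label[match(fam$networks[[1]], hg2$clauses$id)],
               "R <- S")
})

test_that("all-zero readouts make the empty network optimal", {
  hg <- gate_hg()
  exps <- experiments(matrix(c(1L, 0L, 1L, 0L), 2,
                             dimnames = list(NULL, c("S", "I"))),
                      matrix(c(0, 0), 2, dimnames = list(NULL, "R")))
  fam <- learn_networks(hg, exps)
  expect_equal(fam$size, 0)
  expect_equal(fam$mse, 0)
  expect_equal(fam$networks, list(integer(0)))
})

test_that("symmetric clauses yield a two-network family and two behaviors", {
  # S1 and S2 always clamped equal: R <- S1 and R <- S2 are indistinguishable
  net <- suppressWarnings(pkn(data.frame(source = c("S1", "S2"), sign = 1,
                                         target = "R")))
  hg <- expand_hypergraph(net, max_inputs = 1)
  exps <- experiments(matrix(c(1L, 0L, 1L, 0L), 2,
                             dimnames = list(NULL, c("S1", "S2"))),
                      matrix(c(1, 0), 2, dimnames = list(NULL, "R")))
  fam <- learn_networks(hg, exps)
  expect_equal(length(fam$networks), 2)
  fam <- classify_behaviors(fam)
  # on the full clamping space S1 != S2 exists, so behaviors differ
  expect_equal(length(unique(fam$behaviors)), 2)
})

test_that("learning equals brute-force enumeration on random hypergraphs", {
  set.seed(202)
  for (rep in 1:15) {
    inst <- random_learn_instance(max_clauses = 8, n_exp = 5)
    fam <- learn_networks(inst$hg, inst$exps)
    oracle <- oracle_learn(inst$pkn$nodes, inst$cand,
                           inst$exps$clamped, inst$exps$observed)
    expect_equal(fam$mse, oracle$mse, tolerance = 1e-12)
    expect_equal(fam$size, oracle$size)
    got <- lapply(fam$networks, sort)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(oracle$subsets, paste, collapse = ","))
  }
})

test_that("planted networks are recovered from noise-free full coverage", {
  set.seed(301)
  for (rep in 1:5) {
    inst <- random_learn_instance(max_clauses = 10, n_exp = 4)
    truth_ids <- vapply(split(inst$cand$id, inst$cand$target),
                        function(ids) ids[1], integer(1))
    truth <- boolean_network(inst$hg, truth_ids)
    inputs <- colnames(inst$exps$clamped)
    clamp <- bnstrat:::all_clampings(inputs)
    obs <- do.call(rbind, lapply(seq_len(nrow(clamp)), function(e) {
      fixpoint(truth, clamp[e, ])[colnames(inst$exps$observed)]
    }))
    colnames(obs) <- colnames(inst$exps$observed)
    fam <- learn_networks(inst$hg, experiments(clamp, obs))
    expect_equal(fam$mse, 0)
    # the planted behavior is in the family: some member predicts the
    # observations exactly on every covered clamping
    joint <- fam
    joint$networks <- c(fam$networks, list(truth$clauses))
    joint <- classify_behaviors(joint)
    truth_grp <- joint$behaviors[length(joint$behaviors)]
    expect_true(truth_grp %in% joint$behaviors[-length(joint$behaviors)])
  }
})

test_that("family prediction averages member fixpoints", {
  net2 <- pkn(data.frame(source = "S", sign = c(1, -1), target = "R"))
  hg2 <- expand_hypergraph(net2)
  fam <- structure(list(hypergraph = hg2,
                        networks = list(hg2$clauses$id[hg2$clauses$sign1 == 1],
                                        hg2$clauses$id[hg2$clauses$sign1 == -1]),
                        mse = 0.25, size = 1, inputs = "S", readouts = "R",
                        behaviors = NULL),
                   class = "bn_family")
  p <- predict(fam, c(S = 1))
  expect_equal(unname(p["R"]), 0.5)  # one member says 1, the other 0
  single <- fam
  single$networks <- fam$networks[1]
  expect_equal(unname(predict(single, c(S = 1))["R"]), 1)
  fam_b <- classify_behaviors(fam)
  expect_equal(unname(predict(fam_b, c(S = 1), aggregate = "behaviors")["R"]),
               0.5)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("mse matches hand computation and is bounded by 1", {
  net2 <- pkn(data.frame(source = "S", sign = c(1, -1), target = "R"))
  hg2 <- expand_hypergraph(net2)
  pos <- boolean_network(hg2, hg2$clauses$id[hg2$clauses$sign1 == 1])
  exps <- experiments(matrix(1L, 1, dimnames = list(NULL, "S")),
                      matrix(0.5, 1, dimnames = list(NULL, "R")))
  expect_equal(mse(pos, exps), 0.25)
  exact <- experiments(matrix(c(1L, 0L), 2, dimnames = list(NULL, "S")),
                       matrix(c(1, 0), 2, dimnames = list(NULL, "R")))
  expect_equal(mse(pos, exact), 0)
  worst <- experiments(matrix(c(1L, 0L), 2, dimnames = list(NULL, "S")),
                       matrix(c(0, 1), 2, dimnames = list(NULL, "R")))
  expect_lte(mse(pos, worst), 1)
})

test_that("behavior grouping matches truth-table equivalence", {
  # R <- A OR (A AND B) is logically R <- A
  net <- suppressWarnings(pkn(data.frame(source = c("A", "B"), sign = 1,
                                         target = "R")))
  hg <- expand_hypergraph(net)
  idA <- hg$clauses$id[hg$clauses$label == "R <- A"]
  idAB <- hg$clauses$id[hg$clauses$label == "R <- A & B"]
  fam <- structure(list(hypergraph = hg,
                        networks = list(idA, c(idA, idAB)),
                        mse = 0, size = 1, inputs = c("A", "B"),
                        readouts = "R", behaviors = NULL),
                   class = "bn_family")
  fam <- classify_behaviors(fam)
  expect_equal(length(unique(fam$behaviors)), 1)
  # whereas R <- A vs R <- !A differ
  net2 <- pkn(data.frame(source = "A", sign = c(1, -1), target = "R"))
  hg2 <- expand_hypergraph(net2)
  fam2 <- structure(list(hypergraph = hg2,
                         networks = list(hg2$clauses$id[1], hg2$clauses$id[2]),
                         mse = 0, size = 1, inputs = "A", readouts = "R",
                         behaviors = NULL),
                    class = "bn_family")
  expect_equal(length(unique(classify_behaviors(fam2)$behaviors)), 2)
})

test_that("clause frequencies and union network are consistent", {
  net <- suppressWarnings(pkn(data.frame(source = c("A", "B"), sign = 1,
                                         target = "R")))
  hg <- expand_hypergraph(net)
  ids <- hg$clauses$id
  fam <- structure(list(hypergraph = hg,
                        networks = list(ids[1], ids[1:2], c(ids[1], ids[3]),
                                        ids[1:3], ids[1]),
                        mse = 0, size = 1, inputs = c("A", "B"),
                        readouts = "R", behaviors = NULL),
                   class = "bn_family")
  freq <- clause_frequencies(fam)
  expect_equal(freq$frequency[freq$id == ids[1]], 1)
  expect_equal(freq$frequency[freq$id == ids[2]], 0.4)
  expect_true(all(freq$frequency > 0 & freq$frequency <= 1))
  expect_equal(freq$frequency, sort(freq$frequency, decreasing = TRUE))
  un <- union_network(fam)
  expect_setequal(un$clauses, ids)
  # a frequency-1 clause is in the union; singleton family unions to itself
  expect_true(ids[1] %in% un$clauses)
  single <- fam
  single$networks <- list(ids[1:2])
  expect_equal(union_network(single)$clauses, sort(ids[1:2]))
})

test_that("network serialization writes JSON and extended SIF", {
  hg <- gate_hg()
  net <- boolean_network(hg, hg$clauses$id)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, jpath)
  obj <- jsonlite::read_json(jpath)
  expect_equal(obj$type, "network")
  expect_equal(length(obj$clauses), 3)
  spath <- withr::local_tempfile(fileext = ".sif")
  write_network_sif(net, spath)
  lines <- readLines(spath)
  expect_true(any(grepl("^AND:", lines)))   # the 2-literal gate
  expect_true(any(grepl("^S\t1\tR$", lines)))
})

test_that("the exhaustive cap refuses oversized catalogues", {
  set.seed(404)
  inst <- random_learn_instance(max_clauses = 8, n_exp = 3)
  expect_error(learn_networks(inst$hg, inst$exps, exhaustive_cap = 1),
               "cap")
})
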