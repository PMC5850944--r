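proc_from_bits <- function(bits_cr, bits_pr, readouts_cr = NULL,
                           readouts_pr = NULL) {
  n_cr <- nrow(bits_cr)
  n_pr <- nrow(bits_pr)
  ids <- c(sprintf("c%02d", seq_len(n_cr)), sprintf("p%02d", seq_len(n_pr)))
  inputs <- rbind(bits_cr, bits_pr)
  rownames(inputs) <- ids
  if (is.null(readouts_cr)) {
    readouts_cr <- matrix(0.25, n_cr, 2)
  }
  if (is.null(readouts_pr)) readouts_pr <- matrix(0.75, n_pr, 2)
  ro <- rbind(readouts_cr, readouts_pr)
  rownames(ro) <- ids
  colnames(ro) <- sprintf("R%02d", seq_len(ncol(ro)))
  bnstrat:::new_processed_patients(
    inputs, ro, stats::setNames(rep(c("CR", "PR"), c(n_cr, n_pr)), ids))
}

test_that("affinity is 1 exactly when binarized rows agree on K", {
  m <- matrix(c(1, 1, 0, 0, 0, 1), nrow = 2, byrow = FALSE,
              dimnames = list(c("c1", "p1"), c("X1", "X2", "X3")))
  expect_equal(affinity(m, c("X1", "X2"), "c1", "p1"), 1L)
  expect_equal(affinity(m, c("X1", "X3"), "c1", "p1"), 0L)
  expect_equal(affinity(m, "X1", "c1", "p1"), 1L)
  expect_error(affinity(m, character(0), "c1", "p1"), "non-empty")
  expect_error(affinity(m, "X9", "c1", "p1"), "absent")
})

test_that("maximum matching counts non-redundant couples", {
  shared <- tibble::tibble(cr_patient = c("c1", "c1"),
                           pr_patient = c("p1", "p2"))
  expect_equal(nrow(max_nonredundant_couples(shared)), 1)
  disjoint <- tibble::tibble(cr_patient = c("c1", "c2"),
                             pr_patient = c("p1", "p2"))
  expect_equal(nrow(max_nonredundant_couples(disjoint)), 2)
  # complete bipartite K(5,3): matching saturates the small side
  k53 <- expand.grid(cr_patient = sprintf("c%d", 1:5),
                     pr_patient = sprintf("p%d", 1:3),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(max_nonredundant_couples(k53)), 3)
  expect_equal(nrow(max_nonredundant_couples(shared[0, ])), 0)
})

test_that("readout gap sums absolute couple differences, order-invariant", {
  ro_cr <- matrix(c(1, 1), 1, dimnames = list("c1", c("R1", "R2")))
  ro_pr <- matrix(c(0, 0), 1, dimnames = list("p1", c("R1", "R2")))
  cp <- tibble::tibble(cr_patient = "c1", pr_patient = "p1")
  expect_equal(readout_gap(ro_cr, ro_pr, cp), 2)
  expect_equal(readout_gap(ro_cr, ro_cr, tibble::tibble(cr_patient = "c1",
                                                        pr_patient = "c1")), 0)
  set.seed(5)
  ro2_cr <- matrix(runif(8), 4, dimnames = list(sprintf("c%d", 1:4), c("R1", "R2")))
  ro2_pr <- matrix(runif(8), 4, dimnames = list(sprintf("p%d", 1:4), c("R1", "R2")))
  cps <- tibble::tibble(cr_patient = sprintf("c%d", 1:4),
                        pr_patient = sprintf("p%d", 1:4))
  expect_equal(readout_gap(ro2_cr, ro2_pr, cps),
               readout_gap(ro2_cr, ro2_pr, cps[4:1, ]))
})

test_that("selection picks the protein whose profiles coincide across classes", {
  proc <- proc_from_bits(matrix(c(1, 0), 1, dimnames = list(NULL, c("X1", "X2"))),
                         matrix(c(1, 1), 1, dimnames = list(NULL, c("X1", "X2"))))
  sel <- select_proteins(proc, k = 1)
  expect_equal(sel[[1]]$proteins, "X1")
  expect_equal(sel[[1]]$n_couples, 1)
  expect_error(select_proteins(proc, k = 5), "exceeds")
})

test_that("identical class matrices give a perfect matching at full k", {
  set.seed(9)
  bits <- matrix(rbinom(20, 1, 0.5), 4, dimnames = list(NULL, sprintf("X%d", 1:5)))
  proc <- proc_from_bits(bits, bits)
  sel <- select_proteins(proc, k = 5)
  expect_equal(sel[[1]]$n_couples, 4)
  # every returned couple has affinity 1, no patient repeats
  cp <- sel[[1]]$couples
  expect_false(anyDuplicated(cp$cr_patient) > 0)
  expect_false(anyDuplicated(cp$pr_patient) > 0)
  for (i in seq_len(nrow(cp))) {
    expect_equal(affinity(proc$inputs, sel[[1]]$proteins,
                          cp$cr_patient[i], cp$pr_patient[i]), 1L)
  }
})

test_that("no-couple instances return an empty selection set with warning", {
  proc <- proc_from_bits(matrix(c(0, 0), 1, dimnames = list(NULL, c("X1", "X2"))),
                         matrix(c(1, 1), 1, dimnames = list(NULL, c("X1", "X2"))))
  expect_warning(sel <- select_proteins(proc, k = 2), "no affinity couple")
  expect_length(sel, 0)
})

test_that("selection matches the brute-force oracle on random instances", {
  set.seed(123)
  for (rep in 1:30) {
    n_cr <- sample(2:5, 1)
    n_pr <- sample(2:5, 1)
    n_prot <- sample(3:6, 1)
    proc <- random_proc(n_cr, n_pr, n_prot)
    k <- sample(seq_len(n_prot), 1)
    split <- split_by_class(proc)
    gapmat <- bnstrat:::pairwise_gap(split$CR$readouts, split$PR$readouts)
    oracle <- oracle_select(split$CR$inputs, split$PR$inputs, gapmat, k)
    sel <- suppressWarnings(select_proteins(proc, k))
    if (oracle$size <= 0) {
      expect_length(sel, 0)
    } else {
      expect_equal(sel[[1]]$n_couples, oracle$size)
      expect_equal(sel[[1]]$readout_gap, oracle$gap, tolerance = 1e-9)
    }
  }
})

test_that("k sweep reports couples and redundancy per k", {
  set.seed(77)
  proc <- random_proc(5, 5, 4)
  sw <- sweep_k(proc, 1:4)
  expect_equal(sw$k, 1:4)
  expect_true(all(sw$n_couples >= 0))
  expect_s3_class(sw, "bn_k_sweep")
  expect_equal(nrow(sweep_k(proc, integer(0))), 0)
  # constant inputs: couple count equals min(class sizes) for every k
  proc_const <- proc_from_bits(matrix(1, 3, 2, dimnames = list(NULL, c("X1", "X2"))),
                               matrix(1, 4, 2, dimnames = list(NULL, c("X1", "X2"))))
  sw2 <- sweep_k(proc_const, 1:2)
  expect_equal(sw2$n_couples, c(3L, 3L))
})

test_that("reduced datasets share input rows and carry class readouts", {
  set.seed(15)
  bits <- matrix(rbinom(12, 1, 0.5), 3, dimnames = list(NULL, sprintf("X%d", 1:4)))
  proc <- proc_from_bits(bits, bits,
                         readouts_cr = matrix(runif(6), 3),
                         readouts_pr = matrix(runif(6), 3))
  sel <- select_proteins(proc, k = 4)
  red <- build_reduced_datasets(proc, sel)
  expect_identical(red$CR$clamped, red$PR$clamped)
  expect_equal(nrow(red$CR$clamped), sel[[1]]$n_couples)
  cp <- sel[[1]]$couples
  expect_equal(unname(red$CR$observed),
               unname(proc$readouts[cp$cr_patient, , drop = FALSE]))
  expect_equal(unname(red$PR$observed),
               unname(proc$readouts[cp$pr_patient, , drop = FALSE]))
})
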