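test_that("mean pairwise Jaccard matches hand-enumerated cases", {
  expect_equal(mean_pairwise_jaccard(list(c("a", "b"), c("a", "b"))), 1)
  expect_equal(mean_pairwise_jaccard(list("a", "b", "c")), 0)
  # {a,b}, {a,c}, {a,b,c}: pairs 1/3, 1/2, 2/3 -> mean 5/9... hand: see below
  expect_equal(mean_pairwise_jaccard(list(c("a", "b"), c("a", "c"),
                                          c("a", "b", "c"))),
               (1 / 3 + 2 / 3 + 2 / 3) / 3)
  expect_equal(mean_pairwise_jaccard(list(c("a", "b"), c("a", "c"),
                                          c("a", "b", "c"))), 5 / 9)
  # empty sets are identical
  expect_equal(mean_pairwise_jaccard(list(character(0), character(0))), 1)
  expect_equal(mean_pairwise_jaccard(list(character(0), "a")), 0)
  expect_error(mean_pairwise_jaccard(list("a")), "at least 2")
})

test_that("selection probability counts nonzero coefficients per fold", {
  co <- cbind(c(1, 0, 2), c(0.5, 0, 0), c(-1, 1e-12, 0), c(2, 3, 0),
              c(1, 0, 0))
  pi_hat <- selection_probability(co)
  expect_equal(unname(pi_hat), c(1, 0.2, 0.2))  # 1e-12 is below tolerance
  expect_equal(unname(selection_probability(list(c(0, 1), c(0, 1)))),
               c(0, 1))
  expect_error(selection_probability(list(c(1, 2), c(1, 2, 3))),
               "equal length")
})

test_that("stable set includes the threshold boundary", {
  pi_hat <- c(a = 1.0, b = 0.8, c = 0.79, d = 0)
  expect_equal(names(stable_set(pi_hat, 0.8)), c("a", "b"))
  expect_error(stable_set(pi_hat, 0), "pi_thr")
  expect_error(stable_set(pi_hat, 1.2), "pi_thr")
})

test_that("stability score follows the selected-fraction definition", {
  # feature 1 in all folds, feature 2 in one of five
  sets <- list(c(1, 2), 1, 1, 1, 1)
  pi_hat <- selection_probability(vapply(sets, function(s) {
    as.numeric(seq_len(2) %in% s)
  }, numeric(2)))
  st <- stable_set(pi_hat, 0.8)
  expect_equal(st, c(1L), ignore_attr = TRUE)
  expect_equal(stability_score(sets, st), 0.5)
  # every feature always selected
  all_sets <- replicate(4, 1:3, simplify = FALSE)
  expect_equal(stability_score(all_sets, 1:3), 1)
  # nothing ever selected
  expect_equal(stability_score(list(integer(0), integer(0)), integer(0)), 1)
})

test_that("metrics are fold-order invariant and monotone under duplication", {
  set.seed(7)
  co <- matrix(rbinom(40, 1, 0.4) * rnorm(40), 8, 5)
  perm <- co[, sample(5)]
  expect_equal(mean_pairwise_jaccard(
    apply(abs(co) > 0, 2, which, simplify = FALSE)),
    mean_pairwise_jaccard(apply(abs(perm) > 0, 2, which, simplify = FALSE)))
  expect_equal(sort(selection_probability(co)), sort(selection_probability(perm)))
  # doubling every fold preserves the probabilities exactly, and adding a
  # fold that selects everything can only raise them
  pi0 <- selection_probability(co)
  expect_equal(selection_probability(cbind(co, co)), pi0)
  expect_true(all(selection_probability(cbind(co, 1)) >= pi0 - 1e-12))
})

test_that("metrics agree with naive set-arithmetic oracles on random cases", {
  jaccard_oracle <- function(sets) {
    n <- length(sets)
    vals <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      si <- sets[[i]]; sj <- sets[[j]]
      u <- unique(c(si, sj))
      vals <- c(vals, if (length(u) == 0) 1 else
        sum(u %in% si & u %in% sj) / length(u))
    }
    mean(vals)
  }
  set.seed(99)
  for (case in 1:1000) {
    n_folds <- sample(2:5, 1)
    p <- sample(3:10, 1)
    co <- matrix(rbinom(p * n_folds, 1, runif(1, 0.1, 0.9)) * rnorm(p * n_folds),
                 p, n_folds)
    sets <- apply(abs(co) > COEF_TOL, 2, which, simplify = FALSE)
    expect_equal(mean_pairwise_jaccard(sets), jaccard_oracle(sets))
    # selection probability by direct count
    expect_equal(unname(selection_probability(co)),
                 apply(co, 1, function(r) sum(abs(r) > COEF_TOL)) / n_folds)
    # stability score by direct arithmetic
    pi_hat <- selection_probability(co)
    st <- stable_set(pi_hat, 0.8)
    sel <- unique(unlist(sets))
    want <- if (length(sel) == 0) 1 else mean(sel %in% st)
    expect_equal(stability_score(sets, st), want)
  }
})

test_that("stability_report assembles the full block consistently", {
  co <- cbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 0), c(1, 1, 1))
  rep <- stability_report(co)
  expect_equal(unname(rep$pi_hat), c(1, 0.8, 0.2))
  expect_equal(unname(rep$stable_set), c(1L, 2L))
  expect_equal(rep$stability, 2 / 3)
  expect_true(rep$jaccard >= 0 && rep$jaccard <= 1)
})
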