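test_that("complete separation of two triples gives the printed floor p", {
  kw <- kruskal_wallis(list(measurement_group("healthy", c(1, 2, 3)),
                            measurement_group("oa", c(4, 5, 6))))
  expect_equal(round(kw$H, 3), 3.857)
  expect_equal(round(kw$p, 4), 0.0495)
  expect_identical(kw$df, 1L)
})

test_that("H matches the exhaustive rank oracle on all 3+3 arrangements", {
  combos <- utils::combn(6, 3)
  for (k in seq_len(ncol(combos))) {
    a <- combos[, k]
    b <- setdiff(1:6, a)
    vals <- list(as.numeric(a), as.numeric(b))
    if (length(unique(unlist(vals))) == 1L) next
    kw <- kruskal_wallis(list(measurement_group("a", vals[[1]]),
                              measurement_group("b", vals[[2]])))
    expect_equal(kw$H, kw_H_oracle(vals))
  }
})

test_that("degenerate ranks are refused, not silently NaN", {
  expect_error(kruskal_wallis(list(measurement_group("a", c(2, 2)),
                                   measurement_group("b", c(2, 2)))),
               class = "oatopo_degenerate_ranks")
  expect_error(dunn_bonferroni(list(measurement_group("a", c(1, 1)),
                                    measurement_group("b", c(1, 1)))),
               class = "oatopo_degenerate_ranks")
})

test_that("Bonferroni multiplies by the pair count and caps at one", {
  two <- dunn_bonferroni(list(measurement_group("a", c(1, 3, 5)),
                              measurement_group("b", c(2, 4, 6))))
  expect_equal(two$p_adj, two$p_raw)   # single comparison

  three <- dunn_bonferroni(list(measurement_group("a", c(1, 2, 3)),
                                measurement_group("b", c(2, 3, 4)),
                                measurement_group("c", c(9, 10, 11))))
  expect_equal(three$p_adj, pmin(1, three$p_raw * 3))
  expect_true(all(three$p_adj >= three$p_raw))
  expect_true(all(three$p_adj <= 1))
})

test_that("Dunn z-test agrees with a permutation reference", {
  set.seed(42)
  vals <- list(rnorm(8), rnorm(8), rnorm(8), rnorm(8) + 10)
  groups <- mapply(measurement_group, paste0("g", 1:4), vals,
                   SIMPLIFY = FALSE)
  dn <- dunn_bonferroni(groups)
  # only pairs involving the shifted group are significant
  hit <- dn$group_a == "g4" | dn$group_b == "g4"
  expect_true(all(dn$significant[hit]))
  expect_false(any(dn$significant[!hit]))

  # permutation law of the rank-mean gap for one null pair (g1 vs g2)
  x <- unlist(vals)
  obs <- abs(mean(rank(x)[1:8]) - mean(rank(x)[9:16]))
  B <- 10000
  stat <- replicate(B, {
    idx <- sample(length(x))
    r <- rank(x)[idx]
    abs(mean(r[1:8]) - mean(r[9:16]))
  })
  p_perm <- mean(stat >= obs - 1e-12)
  p_z <- dn$p_raw[dn$group_a == "g1" & dn$group_b == "g2"]
  expect_lt(abs(p_perm - p_z), 0.03)
})

test_that("summaries render mean (SD) in the table style", {
  s <- summarize_groups(list(measurement_group("a", c(3, 4, 5)),
                             measurement_group("b", 5)))
  expect_equal(s$rendered[1], "4.00 (1.00)")
  expect_equal(s$rendered[2], "5.00 (—)")
  expect_identical(s$n, c(3L, 1L))
  m <- summarize_groups(list(measurement_group("mia", c(0.29, 0.545))))
  expect_equal(m$mean, 0.4175)
  expect_match(m$rendered, "^0\\.42 \\(")
})

test_that("group construction rejects bad input", {
  expect_error(measurement_group("a", numeric(0)), class = "oatopo_validation")
  expect_error(measurement_group("a", c(1, Inf)), class = "oatopo_validation")
  expect_error(kruskal_wallis(list(measurement_group("a", 1))),
               class = "oatopo_validation")
})
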