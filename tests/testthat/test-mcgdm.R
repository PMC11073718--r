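test_that("linguistic terms map onto the Saaty 1-9 scale", {
  expect_identical(saaty_value("VH"), 9L)
  expect_identical(saaty_value("VL"), 1L)
  expect_identical(saaty_value(c("VLL", "L", "ML", "M", "MH", "H", "HVH")), 2:8)
  expect_error(saaty_value("XX"), class = "phf_term_error")
})

test_that("criteria weights integrate expert judgements and normalize to 1", {
  cs <- phf_fixture("case-study")
  w <- criteria_weights(cs$problem$importance, cs$problem$expert_weights)
  expect_equal(attr(w, "integrated"), c(C1 = 4.5, C2 = 6.75, C3 = 8, C4 = 2))
  expect_equal(as.numeric(w), c(4.5, 6.75, 8, 2) / 21.25)
  expect_equal(sum(w), 1)

  # single expert, uniform importance -> uniform weights
  u <- criteria_weights(matrix("M", 1, 3))
  expect_equal(as.numeric(u), rep(1 / 3, 3))
})

test_that("expert grids convert term-by-term with the expert weight applied", {
  cs <- phf_fixture("case-study")
  grids <- weighted_numeric_matrices(cs$problem)
  expect_equal(grids$D1["C1", "A1"], 2.25)   # VH at weight 0.25
  expect_equal(grids$D3["C1", "A1"], 2)      # HVH at weight 0.25
  expect_equal(grids$D1["C4", "A3"], 0.25)   # VL at weight 0.25

  # a weight-0 expert contributes zeros
  p0 <- phf_problem(alternatives = "A1", criteria = "C1", directions = "benefit",
                    linguistic = list(D1 = matrix("VH", 1, 1), D2 = matrix("M", 1, 1)),
                    expert_weights = c(1, 0), weights = 1)
  g0 <- weighted_numeric_matrices(p0)
  expect_equal(g0$D2[1, 1], 0)
})

test_that("the group matrix collects the k sorted expert values per cell", {
  cs <- phf_fixture("case-study")
  gm <- group_matrix(weighted_numeric_matrices(cs$problem),
                     cs$problem$alternatives, cs$problem$criteria)
  expect_equal(gm[["A1", "C1"]], c(2, 2, 2.25, 2.25))
  expect_equal(gm[["A3", "C3"]], c(1.25, 1.25, 1.25, 1.25))
  expect_equal(gm[["A2", "C2"]], c(1.25, 1.5, 1.75, 2.25))
  expect_error(group_matrix(list(matrix(1, 2, 2), matrix(1, 3, 2))),
               class = "phf_problem_error")
})

test_that("normalization divides benefit columns by their max and inverts cost columns", {
  cs <- phf_fixture("case-study")
  gm <- group_matrix(weighted_numeric_matrices(cs$problem),
                     cs$problem$alternatives, cs$problem$criteria)
  nm <- normalize_group_matrix(gm, cs$problem$directions, rounding = "paper")
  expect_equal(nm[["A1", "C1"]], c(0.89, 0.89, 1, 1))
  # C2 is a cost criterion: column min 0.75 divided by each value
  expect_equal(nm[["A1", "C2"]], c(0.75, 0.75, 0.75, 0.60))
  expect_equal(nm[["A3", "C3"]], c(0.63, 0.63, 0.63, 0.63))

  prec <- normalize_group_matrix(gm, cs$problem$directions)
  expect_equal(prec[["A1", "C1"]], c(2, 2, 2.25, 2.25) / 2.25)
  # the benefit-column maximum maps to exactly 1 in every column
  for (j in c(1, 3, 4)) {
    expect_equal(max(unlist(prec[, j])), 1)
  }
  # the cost-column minimum's cell also reaches exactly 1
  expect_equal(max(unlist(prec[, 2])), 1)
  expect_true(all(unlist(prec) > 0 & unlist(prec) <= 1))
})

test_that("half-up rounding is used in paper mode (0.625 -> 0.63, 0.875 -> 0.88)", {
  g <- matrix(vector("list", 2), nrow = 2, dimnames = list(c("A1", "A2"), "C1"))
  g[[1, 1]] <- c(1.25, 1.75); g[[2, 1]] <- c(2, 2)
  g <- structure(g, class = "group_hf_matrix", k = 2L)
  nm <- normalize_group_matrix(g, "benefit", rounding = "paper")
  expect_equal(nm[[1, 1]], c(0.63, 0.88))  # 0.625 and 0.875, rounded half-up
})

test_that("equal values merge into probabilities that are multiples of 1/k", {
  g <- matrix(vector("list", 1), 1, 1, dimnames = list("A1", "C1"))
  g[[1, 1]] <- c(0.32, 0.32, 0.56, 0.72)
  pm <- to_phf_matrix(structure(g, class = "group_hf_matrix", k = 4L))
  expect_equal(pm[[1, 1]]$m, c(0.32, 0.56, 0.72))
  expect_equal(pm[[1, 1]]$p, c(0.5, 0.25, 0.25))

  g[[1, 1]] <- rep(0.4, 4)
  pm2 <- to_phf_matrix(structure(g, class = "group_hf_matrix", k = 4L))
  expect_equal(pm2[[1, 1]]$m, 0.4)
  expect_equal(pm2[[1, 1]]$p, 1)

  # probabilities always sum to 1 and are multiples of 1/k
  cs <- phf_fixture("case-study")
  gm <- group_matrix(weighted_numeric_matrices(cs$problem),
                     cs$problem$alternatives, cs$problem$criteria)
  pm3 <- to_phf_matrix(normalize_group_matrix(gm, cs$problem$directions, "paper"))
  for (cell in pm3) {
    expect_equal(sum(cell$p), 1)
    expect_true(all(abs(cell$p * 4 - round(cell$p * 4)) < 1e-9))
  }
  expect_equal(pm3[["A1", "C1"]]$m, c(0.89, 1))
  expect_equal(pm3[["A1", "C1"]]$p, c(0.5, 0.5))
})

test_that("the ideal alternative takes the best-scoring cell per criterion", {
  cs <- phf_fixture("case-study-phf")
  ideal <- ideal_alternative(cs$matrix)
  expected <- cs$expected$ideal
  for (j in 1:4) {
    expect_equal(ideal[[j]]$m, expected[[j]]$m)
    expect_equal(ideal[[j]]$p, expected[[j]]$p)
    col_scores <- vapply(1:5, function(i) phf_score(cs$matrix[[i, j]]), numeric(1))
    expect_equal(phf_score(ideal[[j]]), max(col_scores))
  }

  # score ties break toward the lower deviation
  g <- matrix(vector("list", 2), 2, 1, dimnames = list(c("A1", "A2"), "C1"))
  g[[1, 1]] <- phfe(c(0.2, 0.8), c(0.6, 0.4))  # score 0.44, deviation 0.0864
  g[[2, 1]] <- phfe(c(0.6, 0.4), c(0.2, 0.8))  # score 0.44, deviation 0.0064
  id2 <- ideal_alternative(phf_matrix(g))
  expect_equal(id2[[1]]$m, c(0.6, 0.4))
  expect_identical(attr(id2, "source"), 2L)

  # single alternative: its own row
  id3 <- ideal_alternative(phf_matrix(g[1, , drop = FALSE]))
  expect_equal(id3[[1]]$m, c(0.2, 0.8))
})

test_that("ranking orders alternatives by weighted correlation with the ideal", {
  cs <- phf_fixture("case-study-phf")
  rk <- rank_alternatives(cs$matrix, cs$weights)
  expect_close(rk$coefficients, cs$expected$coefficients)
  expect_identical(rk$ordering, cs$expected$ordering)
  expect_length(rk$ties, 0)

  # a duplicated row ties with itself (both match the recomputed ideal
  # perfectly) and ties keep input order
  g <- rbind(cs$matrix[c("A1", "A1", "A3"), ])
  rownames(g) <- c("X1", "X2", "A3")
  rk2 <- rank_alternatives(phf_matrix(g), cs$weights)
  expect_setequal(rk2$ties, c("X1", "X2"))
  expect_identical(rk2$ordering, c("X1", "X2", "A3"))
  expect_equal(unname(rk2$coefficients[1:2]), c(1, 1))

  # a single alternative correlates perfectly with its own ideal
  rk3 <- rank_alternatives(phf_matrix(cs$matrix["A2", , drop = FALSE]), cs$weights)
  expect_equal(unname(rk3$coefficients), 1)
})

test_that("the full pipeline reproduces the orphan-drug case study in paper mode", {
  cs <- phf_fixture("case-study")
  ev <- phf_evaluate(cs$problem, rounding = "paper")
  expect_close(ev$coefficients, cs$expected$coefficients)
  expect_identical(ev$ranking$ordering, cs$expected$ordering)
  # intermediates exposed for audit
  expect_equal(ev$group[["A1", "C1"]], c(2, 2, 2.25, 2.25))
  expect_equal(ev$phf[["A3", "C4"]]$m, c(0.11, 0.22))
  expect_equal(as.numeric(ev$weights), c(0.21, 0.31, 0.39, 0.09))

  # precise mode keeps the same decision here, with unrounded values
  ev2 <- phf_evaluate(cs$problem, rounding = "precise")
  expect_identical(ev2$ranking$ordering, cs$expected$ordering)
  expect_equal(ev2$phf[["A1", "C1"]]$m, c(2 / 2.25, 1))
})

test_that("weight sensitivity keeps the best and worst alternatives stable", {
  sv <- phf_fixture("sensitivity")
  for (nm in names(sv$scenarios)) {
    rk <- rank_alternatives(sv$matrix, sv$scenarios[[nm]])
    expect_close(unname(rk$coefficients), unname(sv$expected$coefficients[nm, ]))
    expect_identical(rk$ordering, sv$expected$orderings[[nm]])
    expect_identical(rk$ordering[1], "A3")
    expect_identical(rk$ordering[5], "A5")
  }
})

test_that("adding a dominated alternative does not reverse the original order", {
  base <- phf_fixture("case-study-phf")
  base_rk <- rank_alternatives(base$matrix, base$weights)
  for (id in c("rank-reversal-A6", "rank-reversal-A6plus")) {
    fx <- phf_fixture(id)
    rk <- rank_alternatives(fx$matrix, fx$weights)
    expect_identical(rk$ordering, fx$expected$ordering)
    kept <- rk$ordering[rk$ordering %in% base_rk$ordering]
    expect_identical(kept, base_rk$ordering)
  }
})

test_that("problem construction validates shapes, weights and vocabulary", {
  expect_error(phf_problem(alternatives = "A1", criteria = "C1",
                           directions = c("benefit", "cost"),
                           weights = 1,
                           linguistic = list(D1 = matrix("M", 1, 1))),
               class = "phf_problem_error")
  expect_error(phf_problem(alternatives = c("A1", "A2"), criteria = "C1",
                           directions = "benefit", weights = 1,
                           linguistic = list(D1 = matrix("M", 1, 1))),
               class = "phf_problem_error")
  expect_error(phf_problem(alternatives = "A1", criteria = "C1",
                           directions = "benefit", weights = 1,
                           linguistic = list(D1 = matrix("QQ", 1, 1))),
               class = "phf_term_error")
  expect_error(phf_problem(alternatives = "A1", criteria = "C1",
                           directions = "benefit", weights = 1),
               class = "phf_problem_error")
  # missing cell
  m <- matrix(c("M", NA), 2, 1, dimnames = list(c("C1", "C2"), "A1"))
  expect_error(phf_problem(alternatives = "A1", criteria = c("C1", "C2"),
                           directions = c("benefit", "benefit"), weights = c(0.5, 0.5),
                           linguistic = list(D1 = m)),
               class = "phf_problem_error")
})
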