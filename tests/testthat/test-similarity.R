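test_that("alignment places, pads and bounds shifts as specified", {
  d3 <- discretize(random_pwm(3, seed = 1), 10)
  d5 <- discretize(random_pwm(5, seed = 2), 10)

  a <- align_pwms(d3, discretize(random_pwm(3, seed = 3), 10), 0)
  expect_equal(a$width, 3)
  expect_identical(a$first$iweights, d3$iweights)

  b <- align_pwms(d3, d5, 2)
  expect_equal(b$width, 5)
  expect_true(all(b$first$iweights[1:2, ] == 0))
  expect_identical(b$first$iweights[3:5, ], d3$iweights)
  expect_identical(b$second$iweights, d5$iweights)

  c3 <- align_pwms(d3, d5, 4)   # boundary: overlap of one column
  expect_equal(c3$width, 7)
  expect_true(all(c3$first$iweights[1:4, ] == 0))
  expect_true(all(c3$second$iweights[6:7, ] == 0))

  expect_error(align_pwms(d3, d5, 5), "outside")
  expect_error(align_pwms(d3, d5, -3), "outside")

  # negative shift pads the second matrix on the left
  e <- align_pwms(d3, d5, -2)
  expect_equal(e$width, 7)
  expect_true(all(e$second$iweights[1:2, ] == 0))
})

test_that("unpruned joint table conserves mass; identical matrices stay on the diagonal", {
  d <- discretize(random_pwm(4, seed = 5), 15)
  pair <- align_pwms(d, d, 0)
  tab <- joint_score_table(pair, background_gc(0.3))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  expect_true(all(tab$s1 == tab$s2))

  pair2 <- align_pwms(d, discretize(random_pwm(6, seed = 6), 15), 1)
  tab2 <- joint_score_table(pair2, background_uniform())
  expect_equal(sum(tab2$weight), 1, tolerance = 1e-9)
})

test_that("joint table equals the brute-force word histogram (small widths)", {
  for (seed in 1:5) {
    m1 <- discretize(random_pwm(1 + seed %% 4, seed = seed), 30)
    m2 <- discretize(random_pwm(1 + (seed + 2) %% 4, seed = seed + 50), 30)
    bg <- if (seed %% 2) background_uniform() else background_gc(0.4)
    s <- ((seed %% 3) - 1)  # a few shifts incl. negative
    s <- max(1 - nrow(m1$iweights), min(nrow(m2$iweights) - 1, s))
    pair <- align_pwms(m1, m2, s)
    tab <- joint_score_table(pair, bg)
    # enumerate all words of the aligned width
    p <- as.numeric(bg)
    words <- all_words(pair$width)
    s1 <- vapply(words, function(w) score_word(pair$first, w), numeric(1))
    s2 <- vapply(words, function(w) score_word(pair$second, w), numeric(1))
    pr <- vapply(strsplit(words, ""), function(ls)
      prod(p[match(ls, c("A", "C", "G", "T"))]), numeric(1))
    expected <- tapply(pr, paste(s1, s2), sum)
    got <- tab$weight
    names(got) <- paste(tab$s1, tab$s2)
    expect_setequal(names(got), names(expected))
    expect_equal(got[names(expected)], expected, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  }
})

test_that("marginals of the joint table reproduce the 1-D score distributions", {
  m1 <- discretize(random_pwm(4, seed = 8), 20)
  m2 <- discretize(random_pwm(5, seed = 9), 20)
  bg <- background_gc(0.6)
  pair <- align_pwms(m1, m2, 1)
  tab <- joint_score_table(pair, bg)
  for (k in 1:2) {
    s <- if (k == 1) tab$s1 else tab$s2
    mat <- if (k == 1) pair$first else pair$second
    dist <- score_distribution(mat, bg)
    marg <- tapply(tab$weight, s, sum)
    idx <- as.numeric(names(marg)) - dist$offset + 1
    expect_equal(as.vector(marg), dist$mass[idx], tolerance = 1e-9)
    expect_equal(sum(dist$mass[-idx]), 0, tolerance = 1e-12)
  }
})

test_that("pruning never changes the intersection probability", {
  for (seed in 10:14) {
    m1 <- discretize(random_pwm(5, seed = seed), 25)
    m2 <- discretize(random_pwm(4, seed = seed + 7), 25)
    bg <- background_uniform()
    t1 <- threshold_from_pvalue(m1, 0.03, bg)$threshold
    t2 <- threshold_from_pvalue(m2, 0.03, bg)$threshold
    pair <- align_pwms(m1, m2, -1)
    full <- joint_score_table(pair, bg, prune = FALSE)
    pruned <- joint_score_table(pair, bg, t1 = t1, t2 = t2, prune = TRUE)
    expect_identical(intersection_probability(pruned, t1, t2),
                     intersection_probability(full, t1, t2))
    expect_lte(length(pruned$weight), length(full$weight))
  }
})

test_that("single-alignment Jaccard matches the worked single-letter sets", {
  wp <- worked_pair_m1()
  pair <- align_pwms(wp$d1, wp$d2, 0)

  r <- jaccard_aligned(pair, wp$t1, wp$t2)
  expect_equal(r$p_intersection, 0.25)  # only "A" passes both
  expect_equal(r$p1, 0.5)
  expect_equal(r$p2, 0.5)
  expect_equal(r$jaccard, 1 / 3)

  # disjoint sets: {A} vs {T}
  dA <- discretize(pwm(matrix(c(1, 0, 0, 0), 1, 4)), 1)
  dT <- discretize(pwm(matrix(c(0, 0, 0, 1), 1, 4)), 1)
  r0 <- jaccard_aligned(align_pwms(dA, dT, 0), 1, 1)
  expect_equal(r0$jaccard, 0)

  # a model against itself
  d <- discretize(random_pwm(3, seed = 15), 10)
  t <- threshold_from_pvalue(d, 0.1)$threshold
  expect_equal(jaccard_aligned(align_pwms(d, d, 0), t, t)$jaccard, 1)

  # intersection boundary cases
  tab <- joint_score_table(pair, background_uniform())
  expect_equal(intersection_probability(tab, wp$d1$min_score, wp$d2$min_score), 1)
  expect_equal(intersection_probability(tab, wp$d1$max_score + 1, wp$t2), 0)
})

test_that("appending zero columns to both aligned matrices leaves J1 unchanged (Lemma 3)", {
  m1 <- random_pwm(4, seed = 16)
  m2 <- random_pwm(5, seed = 17)
  bg <- background_gc(0.45)
  d1 <- discretize(m1, 20); d2 <- discretize(m2, 20)
  t1 <- threshold_from_pvalue(d1, 0.02, bg)$threshold
  t2 <- threshold_from_pvalue(d2, 0.02, bg)$threshold
  base <- jaccard_aligned(align_pwms(d1, d2, 1), t1, t2, bg)
  d1e <- discretize(extend_zero_columns(m1, 2, 1), 20)
  d2e <- discretize(extend_zero_columns(m2, 1, 2), 20)
  # same relative placement of the original columns: core of m1 started at
  # column 2 (shift 1); after padding (2 left on m1, 1 left on m2) it must
  # start at the same core-relative offset -> shift 0
  ext <- jaccard_aligned(align_pwms(d1e, d2e, 0), t1, t2, bg)
  expect_identical(base$jaccard, ext$jaccard)
  expect_identical(base$p_intersection, ext$p_intersection)
})

test_that("jaccard_best finds identity, reverse complements and compensating shifts", {
  x <- random_pwm(6, seed = 18)
  r <- jaccard_best(x, x, pvalue = 0.01)
  expect_equal(r$jaccard, 1)
  expect_equal(r$distance, 0)
  expect_equal(r$shift, 0L)
  expect_equal(r$orientation, "direct")

  rc <- jaccard_best(x, reverse_complement(x), pvalue = 0.01)
  expect_equal(rc$jaccard, 1)
  expect_equal(rc$orientation, "revcomp")

  pad <- jaccard_best(x, extend_zero_columns(x, 1, 2), pvalue = 0.01)
  expect_equal(pad$jaccard, 1)
  expect_equal(pad$shift, 1L)

  expect_error(jaccard_best(x, x, bg = background(0.4, 0.3, 0.2, 0.1)),
               "symmetric")
  # single-strand search accepts an asymmetric background
  r1 <- jaccard_best(x, x, bg = background(0.4, 0.3, 0.2, 0.1),
                     both_strands = FALSE, pvalue = 0.01)
  expect_equal(r1$jaccard, 1)
})

test_that("DP similarity equals the enumeration oracle over all alignments", {
  set.seed(200)
  bgs <- list(background_uniform(), background_gc(0.7))
  for (seed in 1:12) {
    m1 <- discretize(random_pwm(sample(1:5, 1), seed = seed), 100)
    m2 <- discretize(random_pwm(sample(1:5, 1), seed = seed + 500), 100)
    bg <- bgs[[1 + seed %% 2]]
    t1 <- threshold_from_pvalue(m1, 0.05, bg)$threshold
    t2 <- threshold_from_pvalue(m2, 0.05, bg)$threshold
    bf <- brute_force_jaccard(m1, m2, t1, t2, bg)
    dp <- jaccard_best(m1, m2, bg = bg, ithresholds = c(t1, t2))
    expect_equal(dp$jaccard, bf$jaccard, tolerance = 1e-12)
    expect_equal(dp$p_intersection, bf$p_intersection, tolerance = 1e-12)
  }
})

test_that("result invariants hold and ties prefer the direct orientation", {
  # palindromic self-comparison must report the direct orientation
  half <- random_pwm(3, seed = 19)
  pal <- pwm(rbind(half$weights, reverse_complement(half)$weights),
             name = "palindrome")
  r <- jaccard_best(pal, pal, pvalue = 0.01)
  expect_equal(r$jaccard, 1)
  expect_equal(r$orientation, "direct")
  expect_equal(r$shift, 0L)

  x <- random_pwm(5, seed = 20)
  y <- random_pwm(7, seed = 21)
  r <- jaccard_best(x, y, pvalue = 0.05, keep_alignments = TRUE)
  expect_equal(nrow(r$alignments), 2 * (5 + 7 - 1))
  expect_equal(r$jaccard, max(r$alignments$jaccard))
  expect_gte(r$p_union + 1e-12, max(r$p1, r$p2))
  expect_lte(r$p_intersection, min(r$p1, r$p2) + 1e-12)
  expect_gte(r$jaccard, 0)
  expect_lte(r$jaccard, 1)
})

test_that("distance is symmetric and discretization only mildly perturbs J2", {
  x <- random_pwm(5, seed = 22)
  y <- random_pwm(6, seed = 23)
  expect_equal(tfbs_distance(x, y, pvalue = 0.01),
               tfbs_distance(y, x, pvalue = 0.01), tolerance = 1e-12)
  expect_equal(tfbs_distance(x, x, pvalue = 0.01), 0)

  j_coarse <- jaccard_best(x, y, d = 100, pvalue = 0.05)$jaccard
  j_fine <- jaccard_best(x, y, d = 1000, pvalue = 0.05)$jaccard
  expect_lt(abs(j_coarse - j_fine), 0.05)
})
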