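# Shared tiny fixtures, all built in code.

# single-position worked pair: model 1 recognizes {A, C} at t = 1
# (weights A=2, C=1, G=0, T=-1), model 2 recognizes {A, T} at t = 5
# (weights A=5, C=-1, G=-1, T=5); under the uniform background the
# intersection {A} has probability 0.25 and J1 = 1/3
worked_pair_m1 <- function() {
  list(d1 = discretize(pwm(matrix(c(2, 1, 0, -1), 1, 4), name = "w1"), 1),
       d2 = discretize(pwm(matrix(c(5, -1, -1, 5), 1, 4), name = "w2"), 1),
       t1 = 1, t2 = 5)
}

# all words of length m, in the enumeration order A, C, G, T per position
all_words <- function(m) {
  g <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), m))
  apply(as.matrix(g), 1, paste, collapse = "")
}

expect_pwm_equal <- function(a, b) {
  expect_equal(a$weights, b$weights)
  expect_identical(a$width, b$width)
}
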