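test_that("distances, eccentricities and irregularity behave on small graphs", {
  p3 <- generate_graph("path", 3)
  d <- all_pairs_distances(p3)
  expect_equal(d[1, 3], 2L)
  expect_equal(d[1, 2], 1L)
  expect_true(isSymmetric(unname(d)))
  expect_true(all(diag(d) == 0L))

  star <- generate_graph("star", 5)  # K_{1,4}
  ec <- eccentricities(star)
  expect_equal(unname(ec), c(1L, 2L, 2L, 2L, 2L))  # centre 1, leaves 2

  c6 <- generate_graph("cycle", 6)
  expect_true(all(eccentricities(c6) == 3L))
  # radius/diameter sanity bound
  for (fam in c("path", "barbell", "random_tree")) {
    g <- generate_graph(fam, 11, seed = 3)
    ec <- eccentricities(g)
    expect_lte(max(ec), 2L * min(ec))
  }

  # star centre: all neighbours degree 1 -> one distinct value
  expect_equal(irregularity_index(star, 1L), 1L)
  # P4 vertex adjacent to a leaf sees degrees {1, 2} -> 2
  p4 <- generate_graph("path", 4)
  expect_equal(irregularity_index(p4, 2L), 2L)
  # alternative reading counts neighbours with degree != own
  expect_equal(irregularity_index(star, 1L, method = "differing-degree"), 4L)
})

test_that("vertex scores classify and score external and internal vertices", {
  p2 <- generate_graph("path", 2)
  vs <- vertex_scores(p2)
  expect_true(all(vs$klass == "external"))
  expect_equal(vs$score, c(1, 1))

  c4 <- generate_graph("cycle", 4)
  vs4 <- vertex_scores(c4)
  expect_true(all(vs4$klass == "internal"))
  expect_equal(vs4$score, rep(1, 4))  # (t/deg)*ec = (1/2)*2

  taxi <- taxifolin_graph()
  vst <- vertex_scores(taxi)
  expect_equal(sum(vst$score[vst$klass == "external"]), 196)
  # external scores are integers; internal ones are rationals with small denom
  expect_true(all(vst$score[vst$klass == "external"] == round(vst$score[vst$klass == "external"])))
})

test_that("taxifolin worked example fixes both conventions", {
  a <- compute_activity(taxifolin_graph())
  expect_identical(a$external_numerator, 196L)
  expect_equal(round(a$internal_numerator, 4), 85.8333)
  expect_equal(a$D, 196 / 22^3)
  # the alternative irregularity reading does NOT reproduce the example
  b <- compute_activity(taxifolin_graph(), method = "differing-degree")
  expect_false(isTRUE(all.equal(round(b$internal_numerator, 4), 85.8333)))
})

test_that("cycles have zero external activity and floor(n/2)/(2n) internal activity", {
  a6 <- compute_activity(generate_graph("cycle", 6))
  expect_identical(a6$external_numerator, 0L)
  expect_equal(a6$zeta, 0.25)
  for (n in 3:12) {
    a <- compute_activity(generate_graph("cycle", n))
    expect_equal(a$D, 0, info = paste("C", n))
    expect_equal(a$zeta, cycle_zeta(n), info = paste("C", n))
  }
  # P2 has no internal vertex: zeta = 0
  expect_equal(compute_activity(generate_graph("path", 2))$zeta, 0)
})

test_that("star closed forms hold for all k up to 12", {
  for (k in 2:12) {
    a <- compute_activity(generate_graph("star", k + 1))
    expect_equal(a$D, star_D(k), info = paste("star k =", k))
    expect_equal(a$zeta, star_zeta(k), info = paste("star k =", k))
  }
})

test_that("external numerator doubles the unordered end-pair distance sum", {
  for (seed in 1:10) {
    g <- generate_graph("random_tree", 14, seed = seed)
    d <- all_pairs_distances(g)
    S <- which(degrees(g) == 1L)
    pair_sum <- 0L
    for (i in seq_along(S)) for (j in seq_along(S)) {
      if (i < j) pair_sum <- pair_sum + d[S[i], S[j]]
    }
    a <- compute_activity(g)
    expect_identical(a$external_numerator, 2L * pair_sum,
                     info = paste("seed", seed))
  }
})

test_that("activity indices are invariant under vertex relabelling", {
  taxi <- taxifolin_graph()
  a0 <- compute_activity(taxi)
  set.seed(42)
  for (rep in 1:8) {
    perm <- sample(taxi$n)
    g2 <- molecular_graph(cbind(perm[taxi$edges[, 1]], perm[taxi$edges[, 2]]),
                          name = "permuted")
    a2 <- compute_activity(g2)
    expect_identical(a2$external_numerator, a0$external_numerator)
    expect_equal(a2$internal_numerator, a0$internal_numerator)
  }
})

test_that("zeta obeys the coarse eccentricity bound", {
  for (seed in 1:10) {
    g <- generate_graph("random_connected", 12, seed = seed)
    a <- compute_activity(g)
    nQ <- sum(degrees(g) > 1L)
    expect_gte(a$zeta, 0)
    expect_lte(a$zeta, max(eccentricities(g)) * nQ / g$n^2)
  }
})

test_that("activity tables carry exact numerators and 9-dp CSV formatting", {
  graphs <- list(taxifolin_graph(), generate_graph("cycle", 6))
  tab <- activity_table(graphs)
  expect_equal(tab$external_numerator, c(196L, 0L))
  path <- tempfile(fileext = ".csv")
  write_activity_csv(tab, path)
  out <- readLines(path)
  expect_match(out[2], "0.018407213", fixed = TRUE)
  expect_match(out[2], "0.177341598", fixed = TRUE)
})
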