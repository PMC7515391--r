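bucket5 <- fixture_graph("bucket5")

test_that("pair neighborhoods carry the Cannikin quantities", {
  pn <- pair_neighborhood(bucket5, "1", "4")
  expect_equal(pn, list(adjacent = 0L, cn_count = 1L, max_cn_degree = 3L,
                        min_transfer = 0.5))
  pn2 <- pair_neighborhood(bucket5, "3", "2")
  expect_equal(pn2$adjacent, 1L)
  expect_equal(pn2$cn_count, 1L)
  expect_equal(pn2$min_transfer, 0.5)
  pn3 <- pair_neighborhood(bucket5, "1", "5")
  expect_equal(pn3$cn_count, 0L)
  expect_true(is.na(pn3$max_cn_degree))
  expect_equal(pn3$min_transfer, 0)
  expect_error(pair_neighborhood(bucket5, "2", "2"), "distinct")
})

test_that("information capacity follows the bucket formula with 0^0 = 1", {
  expect_equal(information_capacity(bucket5, "1", "4", 1), 0.5)
  expect_equal(information_capacity(bucket5, "3", "2", 1), 1.5)
  expect_equal(information_capacity(bucket5, "1", "5", 2), 0)
  expect_equal(information_capacity(bucket5, "1", "5", 0), 1)
  expect_error(information_capacity(bucket5, "1", "4", -1), "non-negative")
})

test_that("PIC sums channel capacities over both endpoints' neighbors", {
  expect_equal(pic_score(bucket5, "1", "3", 1), 3.0)
  expect_equal(pic_score(bucket5, "1", "5", 1), 1.0)
  expect_equal(pic_score(bucket5, "1", "5", 0), 2.0)
  expect_error(pic_score(bucket5, "1", "zz", 1), "unknown node")
})

test_that("PIC at beta = 0 equals k_x + k_y for non-adjacent pairs", {
  for (s in 1:20) {
    g <- rand_net(8, 0.35, seed = 100 + s)
    A <- adj_of(g)
    k <- rowSums(A)
    labs <- igraph::V(g)$name
    S <- score_all(g, "PIC", beta = 0)
    for (r in seq_len(nrow(S))) {
      i <- match(S$node_u[r], labs); j <- match(S$node_v[r], labs)
      expect_identical(S$score[r], k[[i]] + k[[j]])
    }
  }
})

test_that("local index examples match hand enumeration", {
  expect_equal(cn_score(bucket5, "1", "3"), 1)
  expect_equal(cn_score(bucket5, "1", "5"), 0)
  expect_equal(ra_score(bucket5, "1", "3"), 1 / 3)
  expect_equal(aa_score(bucket5, "1", "3"), 1 / log(3))
  expect_equal(car_score(bucket5, "1", "3"), 0)
  expect_equal(pa_score(bucket5, "1", "3"), 2)

  k4 <- fixture_graph("k4")
  expect_equal(cn_score(k4, "1", "2"), 2)
  expect_equal(ra_score(k4, "1", "2"), 2 / 3)
  expect_equal(aa_score(k4, "1", "2"), 2 / log(3))
  expect_equal(car_score(k4, "1", "2"), 2)
  expect_equal(pa_score(k4, "1", "2"), 9)
})

test_that("adding a degree-2 common neighbor never decreases the capacity", {
  for (s in 1:25) {
    g <- rand_net(9, 0.3, seed = 200 + s)
    before <- information_capacity(g, "1", "2", 1.7)
    g2 <- igraph::add_vertices(g, 1, name = "w")
    g2 <- igraph::add_edges(g2, c("w", "1", "w", "2"))
    after <- information_capacity(g2, "1", "2", 1.7)
    expect_gte(after, before)
  }
})

test_that("every index is symmetric in its endpoints", {
  g <- rand_net(12, 0.3, seed = 77)
  for (idx in c("PIC", "CN", "RA", "AA", "CAR", "PA", "LP", "Katz", "ACT", "Cos+")) {
    S <- piclink:::.score_matrix(g, idx, beta = 1.3, alpha = 0.01, epsilon = 0.05)
    expect_equal(S, t(S), tolerance = 1e-12)
  }
  # pairwise routes too
  expect_equal(pic_score(g, "3", "7", 0.8), pic_score(g, "7", "3", 0.8))
  expect_equal(ra_score(g, "2", "9"), ra_score(g, "9", "2"))
  expect_equal(car_score(g, "4", "8"), car_score(g, "8", "4"))
})

test_that("LP combines two- and three-step paths", {
  lp <- score_all(bucket5, "LP", alpha = 0.001,
                  candidates = rbind(c("1", "3")))
  expect_equal(lp$score, 1.001)
  # alpha = 0 reduces LP to common neighbors on every candidate
  expect_equal(score_all(bucket5, "LP", alpha = 0)$score,
               score_all(bucket5, "CN")$score)
  # edgeless graph scores 0 everywhere
  g0 <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g0)$name <- as.character(1:4)
  expect_true(all(score_all(g0, "LP")$score == 0))
})

test_that("Katz matches its closed form and series, and flags divergence", {
  k2 <- fixture_graph("k2")
  s <- score_all(k2, "Katz", epsilon = 0.1, candidates = rbind(c("1", "2")))
  expect_equal(s$score, 0.1 / (1 - 0.01), tolerance = 1e-12)

  A <- adj_of(bucket5)
  Sk <- piclink:::.score_matrix(bucket5, "Katz", epsilon = 0.001)
  Or <- oracle_katz_matrix(A, 0.001)
  diag(Or) <- 0
  expect_equal(unname(Sk), unname(Or), tolerance = 1e-12)

  # bucket5 has lambda_max < 3, so epsilon = 1.5 is past the radius
  expect_error(score_all(bucket5, "Katz", epsilon = 1.5), "1/lambda_max")
})

test_that("the Laplacian pseudoinverse matches closed forms and axioms", {
  p3 <- fixture_graph("path3")
  Lp <- spectral_cache(p3)$laplacian_pinv
  expect_equal(unname(Lp),
               matrix(c(5, -1, -4, -1, 2, -1, -4, -1, 5), 3) / 9,
               tolerance = 1e-10)
  k2 <- fixture_graph("k2")
  expect_equal(unname(spectral_cache(k2)$laplacian_pinv),
               matrix(c(1, -1, -1, 1), 2) / 4, tolerance = 1e-10)

  g <- rand_net(10, 0.3, seed = 31)
  A <- adj_of(g)
  L <- diag(rowSums(A)) - A
  Lp2 <- spectral_cache(g)$laplacian_pinv
  expect_equal(L %*% Lp2 %*% L, L, tolerance = 1e-9)       # pinv axiom
  expect_lt(max(abs(rowSums(Lp2))), 1e-9)                  # zero row sums
  expect_equal(Lp2, t(Lp2), tolerance = 1e-9)
})

test_that("commute-time and cosine similarities match the path3/k2 values", {
  sc <- spectral_cache(fixture_graph("path3"))
  expect_equal(act_score(sc, "1", "3"), 0.5, tolerance = 1e-10)
  expect_equal(act_score(sc, "1", "2"), 1.0, tolerance = 1e-10)
  expect_equal(cosplus_score(sc, "1", "3"), -0.8, tolerance = 1e-10)
  expect_equal(cosplus_score(sc, "1", "2"), -1 / sqrt(10), tolerance = 1e-10)
  sk2 <- spectral_cache(fixture_graph("k2"))
  expect_equal(act_score(sk2, "1", "2"), 1.0, tolerance = 1e-10)
  expect_equal(cosplus_score(sk2, "1", "2"), -1.0, tolerance = 1e-10)
})

test_that("isolated nodes score zero under the random-walk indices", {
  g <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g)$name <- as.character(1:4)
  g <- igraph::add_edges(g, c("1", "2"))
  sc <- spectral_cache(g)
  expect_equal(cosplus_score(sc, "1", "3"), 0)
  S <- piclink:::.score_matrix(g, "ACT")
  expect_true(all(is.finite(S)))
})

test_that("score_all dispatches, validates, and keeps deterministic order", {
  s <- score_all(bucket5, "PIC", beta = 1,
                 candidates = rbind(c("1", "3"), c("1", "5")))
  expect_equal(s$score, c(3, 1))
  expect_error(score_all(bucket5, "XX"), "valid indices")
  empty <- score_all(bucket5, "CN", candidates = matrix(character(0), ncol = 2))
  expect_equal(nrow(empty), 0)
  full <- score_all(bucket5, "RA")
  expect_equal(nrow(full), choose(5, 2) - 5)
  expect_false(is.unsorted(paste(full$node_u, full$node_v)))
  expect_true(all(is.finite(full$score)))
})

test_that("matrix routes agree with brute-force oracles on small graphs", {
  for (s in 1:40) {
    n <- sample(3:7, 1)
    g <- rand_net(n, 0.4, seed = 3000 + s)
    A <- adj_of(g)
    labs <- igraph::V(g)$name
    beta <- round(runif(1, 0, 3), 2)
    mats <- list(
      PIC = piclink:::.score_matrix(g, "PIC", beta = beta),
      CN = piclink:::.score_matrix(g, "CN"),
      RA = piclink:::.score_matrix(g, "RA"),
      AA = piclink:::.score_matrix(g, "AA"),
      CAR = piclink:::.score_matrix(g, "CAR"),
      PA = piclink:::.score_matrix(g, "PA"),
      LP = piclink:::.score_matrix(g, "LP", alpha = 0.01)
    )
    for (x in 1:(n - 1)) for (y in (x + 1):n) {
      expect_equal(mats$PIC[x, y], oracle_pic(A, x, y, beta), tolerance = 1e-9)
      expect_equal(mats$CN[x, y], oracle_cn(A, x, y), tolerance = 1e-9)
      expect_equal(mats$RA[x, y], oracle_ra(A, x, y), tolerance = 1e-9)
      expect_equal(mats$AA[x, y], oracle_aa(A, x, y), tolerance = 1e-9)
      expect_equal(mats$CAR[x, y], oracle_car(A, x, y), tolerance = 1e-9)
      expect_equal(mats$PA[x, y], oracle_pa(A, x, y), tolerance = 1e-9)
      expect_equal(mats$LP[x, y], oracle_lp(A, x, y, 0.01), tolerance = 1e-9)
    }
  }
})

test_that("whole-network PIC scoring stays inside its complexity envelope", {
  g <- generate_ba(2000, 2, seed = 17)
  elapsed <- system.time(S <- score_all(g, "PIC", beta = 0.9))["elapsed"]
  expect_equal(nrow(S), choose(2000, 2) - igraph::ecount(g))
  expect_lt(elapsed, 120)  # smoke ceiling, not a benchmark
})
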