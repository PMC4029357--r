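test_that("the signature similarity computes the two-sided readout", {
  genes <- c("g1", "g2", "g3", "g4")
  a <- make_profile("a", setNames(c(0, 1, 0.3, -0.2), genes),
                    sig_entries("g1", 1), variance = 1)
  b <- make_profile("b", setNames(c(3, 0, -0.1, 0.4), genes),
                    sig_entries("g2", 1), variance = 1)
  # S = 1/2 * (dir_g1 * b[g1]/var(b) + dir_g2 * a[g2]/var(a)) = (3 + 1)/2
  expect_equal(pairwise_similarity(a, b), 2)

  b2 <- make_profile("b", setNames(c(-3, 0, -0.1, 0.4), genes),
                     sig_entries("g2", 1), variance = 1)
  a2 <- make_profile("a", setNames(c(0, -1, 0.3, -0.2), genes),
                     sig_entries("g1", 1), variance = 1)
  expect_equal(pairwise_similarity(a2, b2), -2)
})

test_that("the similarity is symmetric on random profiles", {
  set.seed(141)
  genes <- sprintf("g%03d", 1:200)
  for (k in 1:20) {
    mk <- function(nm) {
      cons <- setNames(rnorm(200), genes)
      picks <- sample(genes, 8)
      make_profile(nm, cons, sig_entries(picks, sample(c(-1, 1), 8, TRUE)))
    }
    pa <- mk("a"); pb <- mk("b")
    expect_equal(pairwise_similarity(pa, pb), pairwise_similarity(pb, pa))
  }
})

test_that("distances follow the D_max convention", {
  set.seed(151)
  ds <- generate_dataset(sim_config(n_genes = 3000, n_moas = 2,
                                    drugs_per_moa = 2, samples_per_drug = 3,
                                    signature_size = 30, outlier_rate = 0,
                                    seed = 151))
  null <- build_null(ds$matrix, ds$metadata, 1e5, seed = 151)
  sigs <- select_all_signatures(ds$matrix, ds$metadata, null)
  prof <- build_drug_profiles(ds$matrix, ds$metadata, sigs)
  dm <- distance_matrix(prof)

  expect_equal(dm$D, t(dm$D))
  off <- dm$D[upper.tri(dm$D)]
  expect_true(all(off >= 0))
  expect_equal(min(off), 0)                       # most similar pair at 0
  expect_equal(dm$D_max, max(dm$S[upper.tri(dm$S)]))
  # D_max - S preserves the similarity ordering, reversed
  expect_equal(order(dm$S[upper.tri(dm$S)]), order(-off))

  # planted same-MoA pairs are closer than cross-MoA pairs
  same <- outer(ds$truth$moa_of_drug[dm$drugs], ds$truth$moa_of_drug[dm$drugs], "==")
  expect_lt(max(dm$D[same & upper.tri(dm$D)]), min(dm$D[!same & upper.tri(dm$D)]))
})

test_that("the background threshold is the lower-tail empirical quantile", {
  fake_dm <- function(d) {
    n <- ceiling((1 + sqrt(1 + 8 * length(d))) / 2)
    D <- matrix(0, n, n, dimnames = list(paste0("d", 1:n), paste0("d", 1:n)))
    D[upper.tri(D)] <- d
    D <- D + t(D)
    list(drugs = rownames(D), D = D, S = max(d) - D, D_max = max(d))
  }
  set.seed(161)
  u <- runif(10011)   # 142 drugs -> 10011 pairs
  bg <- background_threshold(fake_dm(u), p_level = 0.01)
  expect_lt(abs(bg$threshold - 0.01), 0.005)

  expect_warning(bg0 <- background_threshold(fake_dm(rep(0.7, 45))),
                 "degenerate")
  expect_equal(bg0$threshold, 0.7)

  # two tight planted pairs among many singletons: threshold separates
  d <- rep(9, 190) + rnorm(190, 0, 0.3)
  dd <- fake_dm(d)
  dd$D[1, 2] <- dd$D[2, 1] <- 0
  dd$D[3, 4] <- dd$D[4, 3] <- 0.05
  bg2 <- background_threshold(dd, p_level = 0.01)
  expect_gt(bg2$threshold, 0.05)
  expect_lt(bg2$threshold, 8)
})

test_that("the reflected background ignores contamination by related pairs", {
  set.seed(171)
  null_part <- rnorm(405, 10, 0.5)
  related <- runif(60, 0, 1)      # 13% of the 465 pairs are truly related
  d <- c(related, null_part)
  n <- 31; D <- matrix(0, n, n, dimnames = list(paste0("d", 1:n), paste0("d", 1:n)))
  D[upper.tri(D)] <- d; D <- D + t(D)
  dm <- list(drugs = rownames(D), D = D, S = max(d) - D, D_max = max(d))
  pooled <- background_threshold(dm, 0.01, method = "pooled")$threshold
  reflected <- background_threshold(dm, 0.01, method = "reflected")$threshold
  expect_lt(pooled, 1)                 # buried inside the related mode
  expect_gt(reflected, 1)              # above every related pair
  expect_lt(reflected, 10)             # below the null bulk
  expect_lt(abs(reflected - qnorm(0.01, 10, 0.5)), 0.5)
})

test_that("cutting the dendrogram at extreme thresholds gives the extremes", {
  set.seed(181)
  n <- 7
  D <- as.matrix(stats::dist(matrix(rnorm(n * 2), n)))
  dimnames(D) <- list(paste0("d", 1:n), paste0("d", 1:n))
  dm <- list(drugs = rownames(D), D = D, S = -D, D_max = 0)
  below <- cluster_moas(dm, threshold = min(D[upper.tri(D)]) - 1e-6)
  expect_length(unique(below), n)
  above <- cluster_moas(dm, threshold = max(D) * 2)
  expect_length(unique(above), 1L)
})

test_that("clustering agrees with a brute-force agglomeration oracle", {
  set.seed(191)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    D <- as.matrix(stats::dist(matrix(rnorm(n * 3), n)))
    dimnames(D) <- list(paste0("d", 1:n), paste0("d", 1:n))
    dm <- list(drugs = rownames(D), D = D, S = -D, D_max = 0)
    h <- quantile(D[upper.tri(D)], runif(1))
    got <- cluster_moas(dm, threshold = h)
    want <- oracle_average_agglomeration(D, h)
    expect_equal(adjusted_rand_index(got, want[names(got)]), 1)
  }
})

test_that("MoA labels do not depend on drug input order", {
  set.seed(201)
  n <- 10
  D <- as.matrix(stats::dist(matrix(rnorm(n * 2), n)))
  dimnames(D) <- list(paste0("d", sprintf("%02d", 1:n)), paste0("d", sprintf("%02d", 1:n)))
  dm <- list(drugs = rownames(D), D = D, S = -D, D_max = 0)
  h <- median(D[upper.tri(D)]) / 2
  part1 <- cluster_moas(dm, h)
  perm <- sample(n)
  D2 <- D[perm, perm]
  dm2 <- list(drugs = rownames(D2), D = D2, S = -D2, D_max = 0)
  part2 <- cluster_moas(dm2, h)
  expect_equal(part2[names(part1)], part1)
})

test_that("network construction finds centers and inter-MoA links", {
  # path MoA a-b-c: only edges ab and bc under threshold -> center is b
  D <- matrix(10, 4, 4, dimnames = list(c("a", "b", "c", "z"), c("a", "b", "c", "z")))
  diag(D) <- 0
  D["a", "b"] <- D["b", "a"] <- 1
  D["b", "c"] <- D["c", "b"] <- 1.5
  D["a", "c"] <- D["c", "a"] <- 4     # above threshold: no direct edge
  dm <- list(drugs = rownames(D), D = D, S = 10 - D, D_max = 10)
  moa_of <- c(a = "MoA1", b = "MoA1", c = "MoA1", z = "MoA2")
  net <- build_network(moa_of, dm, threshold = 3)
  expect_equal(unname(net$centers["MoA1"]), "b")
  expect_equal(unname(net$centers["MoA2"]), "z")   # singleton is its own center
  expect_equal(nrow(net$intra_edges), 2L)
  expect_equal(nrow(net$inter_moa_edges), 0L)

  # one cross-MoA pair forced just under threshold -> exactly one link
  D["c", "z"] <- D["z", "c"] <- 2.9
  dm$D <- D
  net2 <- build_network(moa_of, dm, threshold = 3)
  expect_equal(nrow(net2$inter_moa_edges), 1L)
  expect_equal(net2$inter_moa_edges$distance, 2.9)
})

test_that("betweenness centers match exhaustive shortest-path counting", {
  set.seed(211)
  for (k in 1:8) {
    n <- sample(5:10, 1)
    verts <- paste0("v", sprintf("%02d", 1:n))
    # random connected-ish graph as a thresholded distance matrix
    D <- matrix(10, n, n, dimnames = list(verts, verts))
    diag(D) <- 0
    for (i in 2:n) {          # spanning path keeps the MoA connected
      D[i - 1, i] <- D[i, i - 1] <- runif(1, 0.5, 2)
    }
    extra <- which(upper.tri(D) & D == 10)
    picked <- sample(extra, min(length(extra), n))
    D[picked] <- runif(length(picked), 0.5, 2)
    D <- pmin(D, t(D))
    dm <- list(drugs = verts, D = D, S = 10 - D, D_max = 10)
    net <- build_network(setNames(rep("MoA1", n), verts), dm, threshold = 3)
    edges <- which(upper.tri(D) & D < 3, arr.ind = TRUE)
    btw <- oracle_betweenness(verts, verts[edges[, 1]], verts[edges[, 2]])
    best <- sort(names(btw)[btw == max(btw)])[1]
    expect_equal(unname(net$centers["MoA1"]), best)
  }
})
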