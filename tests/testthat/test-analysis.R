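test_that("cluster block means reproduce hand-computed values", {
  # 2 clusters x 2 neurons; edges chosen so each block mean is hand-checkable
  lab <- c(0L, 0L, 1L, 1L)
  W <- matrix(0, 4, 4)
  adj <- matrix(FALSE, 4, 4)
  W[1, 2] <- 0.2; adj[1, 2] <- TRUE       # intra cluster 0
  W[2, 1] <- 0.4; adj[2, 1] <- TRUE       # intra cluster 0
  W[3, 1] <- 0.6; adj[3, 1] <- TRUE       # cluster 1 <- cluster 0
  W[3, 2] <- 0.0; adj[3, 2] <- TRUE       # existing zero-weight edge counts
  W[1, 3] <- 0.8; adj[1, 3] <- TRUE       # cluster 0 <- cluster 1
  bm <- cluster_block_means(W, lab, adj)
  expect_equal(bm$means[1, 1], 0.3)                  # (0.2 + 0.4) / 2
  expect_equal(bm$means[2, 1], 0.3)                  # (0.6 + 0.0) / 2
  expect_equal(bm$means[1, 2], 0.8)
  expect_true(is.na(bm$means[2, 2]))                 # empty block: NA not 0
  expect_equal(sum(bm$counts), 5)
})

test_that("block means of an identity-structured matrix are diagonal", {
  lab <- rep(0:2, each = 3)
  W <- make_ring_matrix(3, 3, w_intra = 0.5, w_ff = 0)
  bm <- cluster_block_means(W, lab)
  expect_equal(diag(bm$means), rep(0.5, 3))
  expect_true(all(bm$means[row(bm$means) != col(bm$means)] %in% NA))
})

test_that("feedforward ordering summarizes the ring structure", {
  lab <- rep(0:4, each = 2)
  W <- make_ring_matrix(5, 2, w_intra = 0.6, w_ff = 0.3)
  # add a weak feedback band by hand
  o <- feedforward_ordering(cluster_block_means(W, lab))
  expect_equal(o$intra, 0.6)
  expect_equal(o$ff, 0.3)
  expect_true(is.na(o$fb) || o$fb == 0)   # no feedback edges in the fixture
})

test_that("ring-matrix spectrum matches the block-circulant closed form", {
  N_C <- 10; m <- 5; w <- 0.3
  W <- make_ring_matrix(N_C, m, 0, w)
  sp <- full_spectrum(W, N_C)
  roots <- m * w * exp(2i * pi * (0:(N_C - 1)) / N_C)
  ring <- sort(sp$ring)
  expected <- sort(roots)
  expect_lt(max(Mod(ring - expected)), 1e-6)
  # all other eigenvalues are 0
  expect_lt(sp$bulk_radius, 1e-8)
})

test_that("spectrum handles degenerate and invalid inputs", {
  sp0 <- full_spectrum(matrix(0, 6, 6), 3)
  expect_true(all(Mod(sp0$values) == 0))
  expect_error(full_spectrum(matrix(0, 2, 3), 1), "square")
})

test_that("conjugate symmetry holds for random real matrices", {
  set.seed(12)
  for (k in 1:5) {
    W <- matrix(rnorm(400), 20, 20)
    ev <- full_spectrum(W, 4)$values
    # every eigenvalue's conjugate is present
    for (z in ev[Im(ev) > 1e-9]) {
      expect_true(min(Mod(ev - Conj(z))) < 1e-6)
    }
  }
})

test_that("most eigenvalues of an iid balanced matrix fall inside the circular-law radius", {
  set.seed(3)
  n <- 200; sd0 <- 0.05
  W <- matrix(rnorm(n * n, 0, sd0), n, n)
  ev <- full_spectrum(W, 1)$values
  radius <- sqrt(n) * sd0
  expect_gte(mean(Mod(ev) <= radius * 1.05), 0.95)
})

test_that("clock metrics recover a constructed ground-truth raster", {
  rec <- make_sequential_raster(N_C = 10, per_cluster_ms = 15, n_cycles = 6)
  lab <- attr(rec, "cluster_label")
  cm <- clock_metrics(rec, lab)
  expect_equal(cm$status, "ok")
  expect_equal(cm$period_ms, 150, tolerance = 0.02)
  expect_equal(cm$score, 1.0)
  expect_lt(abs(cm$activation_ms - 15) / 15, 0.35)  # smoothing broadens edges
})

test_that("clock metrics tolerate jitter and remain translation invariant", {
  rec <- make_sequential_raster(10, 15, 6, jitter = 1, seed = 2)
  lab <- attr(rec, "cluster_label")
  cm <- clock_metrics(rec, lab)
  expect_lt(abs(cm$period_ms - 150) / 150, 0.02)

  shifted <- rec; shifted$t_ms <- shifted$t_ms + 1234.5
  cm2 <- clock_metrics(shifted, lab)
  expect_equal(cm2$period_ms, cm$period_ms)
  expect_equal(cm2$score, cm$score)
})

test_that("shuffled labels destroy sequentiality", {
  rec <- make_sequential_raster(10, 15, 8)
  lab <- attr(rec, "cluster_label")
  set.seed(9)
  shuffled <- lab[sample(length(lab))]
  cm <- clock_metrics(rec, shuffled)
  # chance level is ~1/N_C; anything below 0.35 is clearly non-sequential
  expect_true(cm$status != "ok" || is.na(cm$score) || cm$score < 0.35)
})

test_that("empty spike records yield an explicit no-dynamics result", {
  empty <- data.frame(population = character(0), neuron = integer(0),
                      t_ms = numeric(0))
  cm <- clock_metrics(empty, rep(0:1, each = 5))
  expect_equal(cm$status, "no sequential dynamics")
  expect_true(is.na(cm$period_ms))
})

test_that("replay decoding round-trips a constructed encoding", {
  # ABCBA at 75 ms elements, lead 25, cycle 450: one spike per element
  seqel <- c("A", "B", "C", "B", "A")
  alphabet <- c("A", "B", "C")
  mk <- function(n_spk) {
    rows <- list()
    for (cyc in 0:2) {
      for (k in seq_along(seqel)) {
        t0 <- cyc * 450 + 25 + (k - 1) * 75 + 10
        rows[[length(rows) + 1L]] <- data.frame(
          population = "R", neuron = match(seqel[k], alphabet),
          t_ms = t0 + seq_len(n_spk) - 1)
      }
    }
    do.call(rbind, rows)
  }
  dec <- decode_replay(mk(1), alphabet, cycle_bounds_ms = c(0, 450, 900, 1350))
  expect_equal(dec$status, "ok")
  expect_true(dec$consistent)
  expect_equal(dec$decoded, seqel)
  expect_true(all(unlist(lapply(dec$cycles, `[[`, "counts")) == 1))

  # doubled spikes: same decoding, counts all 2
  dec2 <- decode_replay(mk(2), alphabet, c(0, 450, 900, 1350))
  expect_equal(dec2$decoded, seqel)
  expect_true(all(unlist(lapply(dec2$cycles, `[[`, "counts")) == 2))
})

test_that("decoding fails explicitly without read-out spikes", {
  empty <- data.frame(population = "E", neuron = 1L, t_ms = 5)
  dec <- decode_replay(empty, c("A", "B"), c(0, 100))
  expect_equal(dec$status, "decode failure")
  expect_false(dec$consistent)
})
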