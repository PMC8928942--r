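test_that("image similarity is the Pearson correlation over pixels", {
  ph <- make_phantom(64, 6, seed = 1)
  expect_equal(image_similarity(ph, ph), 1.0)
  expect_equal(image_similarity(ph, -ph + 3), -1.0)
  # two independent white-noise images stay near the null bound 2/m
  set.seed(1); n1 <- matrix(rnorm(128^2), 128, 128)
  set.seed(2); n2 <- matrix(rnorm(128^2), 128, 128)
  expect_lt(abs(image_similarity(n1, n2)), 0.05)
  expect_error(image_similarity(matrix(1, 64, 64), matrix(2, 64, 64)),
               "constant")
})

test_that("similarity matrix is symmetric with unit diagonal and recovers rotations", {
  ph <- make_phantom(64, 8, seed = 2)
  expect_equal(build_similarity_matrix(list(ph)), matrix(1, 1, 1))
  S <- build_similarity_matrix(list(ph, rotate_image(ph, 40),
                                    shift_image(ph, 2.5, -1.5)))
  expect_equal(S, t(S))
  expect_equal(diag(S), rep(1, 3))
  expect_gt(S[1, 2], 0.97)
  expect_gt(S[1, 3], 0.97)
  expect_error(build_similarity_matrix(list()), "empty")
  expect_error(build_similarity_matrix(list(ph, ph[1:32, 1:32])), "mixed")
})

test_that("adaptive neighborhood size follows the square-root rule with a cap", {
  expect_equal(adaptive_k(10000), 105)
  expect_equal(adaptive_k(100), 15)
  expect_equal(adaptive_k(10), 8)
  expect_equal(adaptive_k(5), 4)      # cap N - 1 engages: 2 + 5 = 7 -> 4
  expect_error(adaptive_k(1), "at least 2")
})

test_that("shared-neighbor counts are set intersections of kNN lists", {
  # hand-built similarity: known neighbor sets
  S <- diag(1, 6)
  S[lower.tri(S)] <- 0
  # image 1 prefers 2,3,4; image 2 prefers 3,4,5 (ties broken by index)
  S[1, 2:6] <- c(0.9, 0.8, 0.7, 0.1, 0.05)
  S[2, 3:6] <- c(0.9, 0.8, 0.7, 0.1)
  S[3, 4:6] <- c(0.5, 0.4, 0.3)
  S[4, 5:6] <- c(0.2, 0.1)
  S[5, 6] <- 0.6
  S <- S + t(S); diag(S) <- 1
  snn <- snn_counts(S, k = 3)
  expect_equal(snn$counts[1, 2], 2L)            # {2,3,4} cap {3,4,5}
  expect_equal(snn$counts, t(snn$counts))
  expect_equal(diag(snn$counts), rep(3L, 6))
  expect_true(all(snn$counts <= 3L))
  expect_error(snn_counts(S, 6), "\\[1, N-1\\]")

  # identical similarity rows share at least k - 1 neighbors
  S2 <- matrix(0.5, 8, 8); diag(S2) <- 1
  S2[1, ] <- S2[, 1] <- c(1, 0.5, 0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  S2[2, ] <- S2[, 2] <- c(0.5, 1, 0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  sn2 <- snn_counts(S2, k = 3)
  expect_gte(sn2$counts[1, 2], 2L)
})

test_that("adjacency binarization uses a strict threshold and zero diagonal", {
  counts <- matrix(c(9, 6, 5, 6, 9, 0, 5, 0, 9), 3, 3)
  AM <- binarize_adjacency(list(counts = counts, k = 9), NS = 5)
  expect_equal(AM[1, 2], 1L)   # 6 > 5
  expect_equal(AM[1, 3], 0L)   # 5 is not > 5
  expect_equal(AM[2, 3], 0L)
  expect_equal(diag(AM), rep(0L, 3))
})

test_that("spectral partition separates disjoint cliques exactly", {
  AM <- matrix(0L, 20, 20)
  AM[1:10, 1:10] <- 1L
  AM[11:20, 11:20] <- 1L
  diag(AM) <- 0L
  part <- spectral_partition(AM, n_classes = 2, seed = 1)
  expect_equal(length(unique(part$labels[1:10])), 1)
  expect_equal(length(unique(part$labels[11:20])), 1)
  expect_false(part$labels[1] == part$labels[11])
  expect_error(spectral_partition(AM, n_classes = 21, seed = 1), "classes")
})

test_that("spectral partition recovers a planted partition and is deterministic", {
  set.seed(42)
  n_blk <- 30
  labels_true <- rep(1:3, each = n_blk)
  N <- 3 * n_blk
  AM <- matrix(0L, N, N)
  for (i in 1:(N - 1)) for (j in (i + 1):N) {
    p <- if (labels_true[i] == labels_true[j]) 0.8 else 0.02
    AM[i, j] <- AM[j, i] <- as.integer(runif(1) < p)
  }
  S <- AM + 0  # similarity stand-in for isolated attachment/medoids
  p1 <- spectral_partition(AM, 3, seed = 7, S = S)
  p2 <- spectral_partition(AM, 3, seed = 7, S = S)
  expect_identical(p1$labels, p2$labels)
  # perfect recovery up to label permutation
  tab <- table(labels_true, p1$labels)
  expect_equal(sum(apply(tab, 1, max)), N)
  # medoids belong to their own class
  for (cl in 1:3) expect_equal(p1$labels[p1$medoids[cl]], cl)
})

test_that("isolated vertices are attached to their most similar neighbor's class", {
  AM <- matrix(0L, 9, 9)
  AM[1:4, 1:4] <- 1L
  AM[5:8, 5:8] <- 1L
  diag(AM) <- 0L                      # vertex 9 is isolated
  S <- matrix(0.1, 9, 9); diag(S) <- 1
  S[9, 5] <- S[5, 9] <- 0.9           # most similar to the second clique
  part <- spectral_partition(AM, 2, seed = 1, S = S)
  expect_equal(part$isolated, 9L)
  expect_equal(part$labels[9], part$labels[5])
  expect_error(spectral_partition(AM, 2, seed = 1), "similarity matrix")
})

test_that("class averages are convex similarity-weighted means", {
  ph <- make_phantom(64, 8, seed = 3)
  # single-member class returns the medoid exactly
  ca1 <- class_average(list(ph), 1)
  expect_equal(ca1$image, ph)
  expect_equal(sum(ca1$member_weights), 1)
  # identical members with similarity 1 reproduce the image
  ca2 <- class_average(list(ph, ph), 1)
  expect_equal(ca2$image, ph, tolerance = 1e-8)
  expect_equal(sum(ca2$member_weights), 1)
  # literal normalization divides by the similarity sum only
  ca3 <- class_average(list(ph, ph), 1, literal_norm = TRUE)
  expect_equal(ca3$image, 2 * ph, tolerance = 1e-8)
  expect_error(class_average(list(), 1), "empty|medoid")
})

test_that("averaging noisy copies cancels noise", {
  ph <- make_phantom(64, 8, seed = 4)
  copies <- c(list(ph), lapply(1:50, function(i) add_noise(ph, 0.1, seed = i)))
  ca <- class_average(copies, 1)
  avg_cor <- image_similarity(ph, ca$image)
  member_cors <- vapply(copies[-1], function(im) image_similarity(ph, im),
                        numeric(1))
  expect_gt(avg_cor, max(member_cors))
  # background variance shrinks relative to the members
  member_var <- mean(vapply(copies[-1],
                            function(im) stats::var(as.vector(im)),
                            numeric(1)))
  expect_lte(stats::var(as.vector(ca$image)), member_var)
})

test_that("the full pipeline chains the stages and reports per-image parameters", {
  stk <- make_class_stack(views = 2, per_view = 6, snr = 1, m = 64, seed = 11)
  cls <- classify_stack(stk$images, n_classes = 2, seed = 11)
  expect_s3_class(cls, "cryo_classes")
  expect_equal(cls$k, adaptive_k(12))
  expect_equal(length(cls$labels), 12)
  expect_equal(cls$S, t(cls$S))
  expect_equal(diag(cls$S), rep(1, 12))
  expect_true(all(cls$labels %in% 1:2))
  # planted two-view recovery at moderate noise
  tab <- table(stk$labels, cls$labels)
  expect_equal(sum(apply(tab, 1, max)), 12)
  # per-image parameters are filled and medoids have identity parameters
  expect_false(any(is.na(cls$params$similarity)))
  for (cl in 1:2) {
    med <- cls$medoids[cl]
    expect_equal(cls$params$theta[med], 0)
    expect_equal(cls$params$similarity[med], 1)
  }
})
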