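#' Pearson similarity between two images
#'
#' The 2D correlation coefficient over all pixels, the similarity used
#' throughout the class-averaging pipeline.
#'
#' @param Mi,Mj numeric m x m matrices of equal size.
#' @return a number in `[-1, 1]`.
#' @export
image_similarity <- function(Mi, Mj) {
  assert_square_image(Mi)
  assert_square_image(Mj)
  assert_same_size(Mi, Mj)
  if (stats::sd(Mi) == 0 || stats::sd(Mj) == 0)
    stop("correlation is undefined for a constant image", call. = FALSE)
  stats::cor(as.vector(Mi), as.vector(Mj))
}

#' Pairwise post-alignment similarity matrix of a stack
#'
#' For every pair of images the second is jointly aligned onto the first
#' with [align_images()] and the Pearson similarity of the reference with
#' the aligned image is recorded. The matrix is symmetric with unit
#' diagonal.
#'
#' @param stack list of numeric m x m matrices (uniform m).
#' @param interpolate use spline peak refinement in the alignments?
#' @param max_iter maximum alignment iterations per pair.
#' @param verbose print progress every 500 pairs?
#' @return an N x N numeric similarity matrix.
#' @export
build_similarity_matrix <- function(stack, interpolate = TRUE,
                                    max_iter = 10L, verbose = FALSE) {
  n <- length(stack)
  if (n < 1) stop("stack is empty", call. = FALSE)
  m <- nrow(stack[[1]])
  for (im in stack) {
    assert_square_image(im)
    if (nrow(im) != m) stop("stack images have mixed sizes", call. = FALSE)
  }
  S <- diag(1, n)
  if (n == 1) return(S)
  done <- 0L
  total <- n * (n - 1L) / 2L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- align_images(stack[[i]], stack[[j]], max_iter = max_iter,
                         interpolate = interpolate)
      S[i, j] <- S[j, i] <- al$corr_after
      done <- done + 1L
      if (verbose && done %% 500L == 0L)
        message(sprintf("similarity: %d / %d pairs", done, total))
    }
  }
  S
}

#' Adaptive neighborhood size for the kNN graph
#'
#' Chooses the number of nearest neighbors from the stack size as
#' `floor(sqrt(N)) + NS`, capped at `N - 1`.
#'
#' @param N number of images (at least 2).
#' @param NS shared-neighbor threshold parameter (default 5).
#' @return integer neighborhood size.
#' @examples
#' adaptive_k(10000)  # 105
#' adaptive_k(100)    # 15
#' @export
adaptive_k <- function(N, NS = 5L) {
  if (N < 2) stop("N must be at least 2", call. = FALSE)
  min(floor(sqrt(N)) + NS, N - 1L)
}

#' Shared-nearest-neighbor counts
#'
#' For each image, its k nearest neighbors (excluding itself, ties broken
#' by lower index) are taken from the similarity matrix; entry (i, j) is
#' the number of neighbors the two sets share. The diagonal is set to k.
#'
#' @param S N x N similarity matrix.
#' @param k neighborhood size, `1 <= k <= N - 1`.
#' @return a list with `counts` (N x N integer matrix) and `k`.
#' @export
snn_counts <- function(S, k) {
  N <- nrow(S)
  if (k < 1 || k > N - 1) stop("k must lie in [1, N-1]", call. = FALSE)
  # membership matrix: B[i, j] = 1 iff j is among the k nearest of i
  B <- matrix(0L, N, N)
  for (i in seq_len(N)) {
    ord <- order(-S[i, ], seq_len(N))
    ord <- ord[ord != i]
    B[i, ord[seq_len(k)]] <- 1L
  }
  counts <- B %*% t(B)
  diag(counts) <- k
  storage.mode(counts) <- "integer"
  list(counts = counts, k = k)
}

#' Binarize shared-neighbor counts into an adjacency matrix
#'
#' Two images are connected when they share strictly more than `NS`
#' nearest neighbors. The diagonal is zero.
#'
#' @param snn result of [snn_counts()] (or a bare counts matrix).
#' @param NS threshold (default 5); the edge rule is `counts > NS`.
#' @return an N x N binary integer matrix.
#' @export
binarize_adjacency <- function(snn, NS = 5L) {
  counts <- if (is.list(snn)) snn$counts else snn
  AM <- (counts > NS) * 1L
  diag(AM) <- 0L
  AM
}

#' Normalized spectral clustering of an adjacency matrix
#'
#' Partitions the graph with the symmetric normalized Laplacian: the
#' eigenvectors of D^(-1/2) A D^(-1/2) for the `n_classes` largest
#' eigenvalues are row-normalized and clustered with seeded k-means.
#' Isolated vertices (zero degree, for which the normalized Laplacian is
#' undefined) are excluded from the eigen-decomposition and attached
#' afterwards to the class of their most similar non-isolated image,
#' which requires `S`.
#'
#' @param AM N x N symmetric binary adjacency matrix.
#' @param n_classes number of classes (at least 2).
#' @param seed integer seed controlling the k-means initialization.
#' @param S optional similarity matrix, used to attach isolated vertices
#'   and to pick class medoids.
#' @return a list of class `"cluster_assignment"` with `labels` (length-N
#'   integer vector in `1..n_classes`), `n_classes`, `medoids` (per-class
#'   index of the member with the largest total within-class similarity;
#'   `NA` when `S` is not supplied), and `isolated` (indices attached
#'   post hoc).
#' @export
spectral_partition <- function(AM, n_classes, seed = 1L, S = NULL) {
  if (n_classes < 2) stop("n_classes must be at least 2", call. = FALSE)
  if (!isTRUE(all(AM == t(AM)))) stop("adjacency must be symmetric", call. = FALSE)
  N <- nrow(AM)
  deg <- rowSums(AM)
  core <- which(deg > 0)
  isolated <- which(deg == 0)
  if (n_classes > length(core))
    stop("more classes requested than connected images", call. = FALSE)
  if (length(isolated) > 0 && is.null(S))
    stop("similarity matrix S required to place isolated images", call. = FALSE)

  A <- AM[core, core, drop = FALSE]
  dinv <- 1 / sqrt(rowSums(A))
  M <- t(A * dinv) * dinv          # D^(-1/2) A D^(-1/2), symmetric
  ev <- eigen(M, symmetric = TRUE)
  U <- ev$vectors[, seq_len(n_classes), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm == 0] <- 1
  U <- U / nrm
  km <- with_seed(seed,
                  stats::kmeans(U, centers = n_classes, nstart = 10L,
                                iter.max = 100L))
  labels <- integer(N)
  labels[core] <- km$cluster
  for (i in isolated) {
    s <- S[i, ]
    s[i] <- -Inf
    s[isolated] <- -Inf
    labels[i] <- labels[which.max(s)]
  }

  medoids <- rep(NA_integer_, n_classes)
  if (!is.null(S)) {
    for (cl in seq_len(n_classes)) {
      members <- which(labels == cl)
      if (length(members) == 0) next
      tot <- rowSums(S[members, members, drop = FALSE])
      medoids[cl] <- members[which.max(tot)]
    }
  }
  structure(list(labels = labels, n_classes = n_classes,
                 medoids = medoids, isolated = isolated),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Cluster assignment: %d images, %d classes\n",
              length(x$labels), x$n_classes))
  print(table(class = x$labels))
  invisible(x)
}

#' Similarity-weighted class average
#'
#' Aligns every class member onto the medoid image, weights each aligned
#' member by its post-alignment similarity to the medoid, adds the medoid
#' itself with weight 1, and normalizes. By default the denominator is
#' `1 + sum(S)` so the weights form a convex combination (a single-member
#' class returns the medoid exactly); `literal_norm = TRUE` divides by
#' `sum(S)` only.
#'
#' @param members list of numeric m x m matrices, the class members.
#' @param medoid_index index of the medoid within `members`.
#' @param interpolate use spline peak refinement in the alignments?
#' @param max_iter maximum alignment iterations.
#' @param literal_norm normalize by the sum of similarities only?
#' @return a list of class `"class_average"` with `image`, `n_members`,
#'   `member_weights` (effective weights, summing to 1 unless
#'   `literal_norm`), and `params` (per-member theta/dx/dy/n_iter/similarity
#'   relative to the medoid).
#' @export
class_average <- function(members, medoid_index, interpolate = TRUE,
                          max_iter = 10L, literal_norm = FALSE) {
  n <- length(members)
  if (n < 1) stop("class is empty", call. = FALSE)
  if (medoid_index < 1 || medoid_index > n)
    stop("medoid_index out of range", call. = FALSE)
  medoid <- members[[medoid_index]]
  assert_square_image(medoid)

  acc <- medoid
  wsum <- 0
  raw_w <- numeric(n)
  raw_w[medoid_index] <- 1
  params <- data.frame(member = seq_len(n), theta = 0, dx = 0, dy = 0,
                       n_iter = 0L, similarity = 1)
  for (i in seq_len(n)) {
    if (i == medoid_index) next
    al <- align_images(medoid, members[[i]], max_iter = max_iter,
                       interpolate = interpolate)
    s <- al$corr_after
    acc <- acc + s * al$aligned
    wsum <- wsum + s
    raw_w[i] <- s
    params[i, c("theta", "dx", "dy")] <- c(al$theta, al$dx, al$dy)
    params$n_iter[i] <- al$n_iter
    params$similarity[i] <- s
  }
  denom <- if (literal_norm) wsum else 1 + wsum
  if (denom == 0) stop("degenerate class: similarity weights sum to zero",
                       call. = FALSE)
  structure(list(image = acc / denom, n_members = n,
                 member_weights = raw_w / denom, params = params),
            class = "class_average")
}

#' @export
print.class_average <- function(x, ...) {
  cat(sprintf("Class average of %d member(s), %d x %d px\n",
              x$n_members, nrow(x$image), ncol(x$image)))
  invisible(x)
}

#' Classify a particle stack into class averages
#'
#' The full 2D classification pipeline: all pairs are jointly aligned to
#' build the similarity matrix, a shared-nearest-neighbor graph is formed
#' with an adaptive neighborhood size and binarized at threshold `NS`,
#' the graph is partitioned with normalized spectral clustering, and each
#' class is re-aligned onto its medoid and averaged with similarity
#' weights.
#'
#' @param stack list of numeric m x m matrices (uniform m).
#' @param n_classes number of classes.
#' @param NS shared-neighbor threshold (default 5).
#' @param seed integer seed for the spectral partition.
#' @param interpolate use spline peak refinement?
#' @param k neighborhood size override; defaults to [adaptive_k()].
#' @param max_iter maximum alignment iterations per pair.
#' @param literal_norm see [class_average()].
#' @param verbose print per-stage progress?
#' @return an object of class `"cryo_classes"`: a list with `labels`,
#'   `medoids`, `averages` (list of [class_average()] results indexed by
#'   class), the similarity matrix `S`, the graph parameters `k` and
#'   `NS`, per-image alignment parameters relative to the class medoid
#'   (`params`), and the `config` used.
#' @examples
#' \donttest{
#' stk <- make_class_stack(views = 2, per_view = 6, snr = 1, m = 64, seed = 1)
#' cls <- classify_stack(stk$images, n_classes = 2, seed = 1)
#' summary(cls)
#' }
#' @export
classify_stack <- function(stack, n_classes, NS = 5L, seed = 1L,
                           interpolate = TRUE, k = NULL, max_iter = 10L,
                           literal_norm = FALSE, verbose = FALSE) {
  N <- length(stack)
  if (N < 2) stop("need at least two images", call. = FALSE)
  if (verbose) message("building similarity matrix (", N, " images)")
  S <- build_similarity_matrix(stack, interpolate = interpolate,
                               max_iter = max_iter, verbose = verbose)
  if (is.null(k)) k <- adaptive_k(N, NS)
  snn <- snn_counts(S, k)
  AM <- binarize_adjacency(snn, NS)
  if (verbose) message("spectral partition into ", n_classes, " classes")
  part <- spectral_partition(AM, n_classes, seed = seed, S = S)

  averages <- vector("list", n_classes)
  params <- data.frame(index = seq_len(N), label = part$labels,
                       theta = NA_real_, dx = NA_real_, dy = NA_real_,
                       n_iter = NA_integer_, similarity = NA_real_)
  for (cl in seq_len(n_classes)) {
    members <- which(part$labels == cl)
    if (length(members) == 0) next
    med_local <- match(part$medoids[cl], members)
    avg <- class_average(stack[members], med_local,
                         interpolate = interpolate, max_iter = max_iter,
                         literal_norm = literal_norm)
    averages[[cl]] <- avg
    params[members, c("theta", "dx", "dy")] <-
      avg$params[, c("theta", "dx", "dy")]
    params$n_iter[members] <- avg$params$n_iter
    params$similarity[members] <- avg$params$similarity
    if (verbose) message(sprintf("class %d: %d member(s)", cl, length(members)))
  }
  structure(list(labels = part$labels, medoids = part$medoids,
                 isolated = part$isolated, averages = averages, S = S,
                 k = k, NS = NS, params = params,
                 config = list(n_classes = n_classes, NS = NS, k = k,
                               seed = seed, interpolate = interpolate,
                               max_iter = max_iter,
                               literal_norm = literal_norm)),
            class = "cryo_classes")
}

#' @export
print.cryo_classes <- function(x, ...) {
  cat(sprintf("2D classification of %d images into %d classes (k = %d, NS = %d)\n",
              length(x$labels), x$config$n_classes, x$k, x$NS))
  print(table(class = x$labels))
  invisible(x)
}

#' @export
summary.cryo_classes <- function(object, ...) {
  sizes <- tabulate(object$labels, nbins = object$config$n_classes)
  cat(sprintf("2D classification: %d images, %d classes\n",
              length(object$labels), object$config$n_classes))
  cat(sprintf("graph: k = %d nearest neighbors, NS = %d, %d isolated image(s)\n",
              object$k, object$NS, length(object$isolated)))
  cat("class sizes:", paste(sizes, collapse = ", "), "\n")
  ok <- !is.na(object$params$similarity)
  cat(sprintf("median similarity to class medoid: %.3f\n",
              stats::median(object$params$similarity[ok])))
  invisible(object)
}

#' Display class averages
#'
#' @param x a `"cryo_classes"` object.
#' @param classes which classes to draw (default all non-empty).
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.cryo_classes <- function(x, classes = NULL, ...) {
  filled <- which(!vapply(x$averages, is.null, logical(1)))
  if (is.null(classes)) classes <- filled
  classes <- intersect(classes, filled)
  if (length(classes) == 0) stop("no class averages to plot", call. = FALSE)
  nc <- ceiling(sqrt(length(classes)))
  nr <- ceiling(length(classes) / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  for (cl in classes) {
    img <- x$averages[[cl]]$image
    graphics::image(t(img[nrow(img):1, ]), axes = FALSE, asp = 1,
                    col = grDevices::gray.colors(256),
                    main = sprintf("class %d (n = %d)", cl,
                                   x$averages[[cl]]$n_members), ...)
  }
  invisible(x)
}
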