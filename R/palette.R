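#' Presence/absence matrix of enrichment found entities
#'
#' Rows are enrichment results (one per pathway x analysis context), columns
#' the union of found-entity genes, entries binary. Row and column order is
#' deterministic (sorted ids / sorted gene symbols).
#'
#' @param results data.frame from [enrich_collection()] (possibly several
#'   row-bound calls) with columns `set`, `query`, `found_entities`; or a
#'   named list of character vectors of found entities.
#' @return Binary matrix with informative rownames. Results with an empty
#'   found-entity set are rejected by name.
#' @export
build_found_entity_matrix <- function(results) {
  if (is.data.frame(results)) {
    ids <- paste(results$query, results$set, sep = "|")
    sets <- strsplit(results$found_entities, ";", fixed = TRUE)
    names(sets) <- ids
  } else {
    sets <- results
  }
  if (length(sets) < 2L) abort_validation("need at least 2 enrichment results")
  empty <- names(sets)[lengths(sets) == 0L | vapply(sets, function(s)
    all(!nzchar(s)), logical(1L))]
  if (length(empty)) {
    abort_validation("empty found-entity set(s): ",
                     paste(empty, collapse = ", "))
  }
  sets <- sets[order(names(sets))]
  genes <- sort(unique(unlist(sets)))
  m <- matrix(0L, length(sets), length(genes),
              dimnames = list(names(sets), genes))
  for (i in seq_along(sets)) m[i, sets[[i]]] <- 1L
  m
}

#' PCA embedding of a presence/absence matrix
#'
#' Column-centred principal components via SVD, ordered by decreasing
#' variance, with the sign convention that each component's
#' largest-magnitude loading is positive. `n_pcs` is capped at the matrix
#' rank (with a warning).
#'
#' @param m numeric matrix, rows = enrichment results.
#' @param n_pcs number of components to keep (default 20).
#' @return Score matrix (rows x kept PCs) with the per-PC standard
#'   deviations as attribute `"sdev"`.
#' @export
pca_embed <- function(m, n_pcs = 20L) {
  if (nrow(m) < 2L) abort_validation("need at least 2 rows")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (rank == 0L) abort_validation("matrix has zero variance")
  if (n_pcs > rank) {
    warning("n_pcs capped at matrix rank ", rank, call. = FALSE)
    n_pcs <- rank
  }
  flip <- vapply(seq_len(n_pcs), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1L))
  scores <- sweep(pc$x[, seq_len(n_pcs), drop = FALSE], 2L, flip, "*")
  attr(scores, "sdev") <- pc$sdev[seq_len(n_pcs)]
  scores
}

# exact (O(n^2)) t-SNE to `dims` dimensions; deterministic given seed.
# Standard formulation: perplexity-calibrated Gaussian input affinities,
# Student-t low-dimensional kernel, gradient descent with momentum and
# early exaggeration.
tsne_exact <- function(x, dims = 3L, perplexity = 30, n_iter = 1000L,
                       seed = 1L) {
  n <- nrow(x)
  if (n < 2L) abort_validation("need at least 2 points")
  d2 <- as.matrix(dist(x))^2
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0 } else {
        pj <- w / sw
        h <- -sum(ifelse(pj > 0, pj * log(pj), 0))
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-di * beta)
    if (sum(w) == 0) w <- rep(1, length(di))
    p[i, -i] <- w / sum(w)
  }
  p <- (p + Matrix::t(p)) / (2 * n)
  p[p < .Machine$double.xmin] <- .Machine$double.xmin
  set.seed(stage_seed(seed, "palette"))
  y <- matrix(rnorm(n * dims, sd = 1e-4), n, dims)
  inc <- matrix(0, n, dims)
  exaggeration <- 12
  momentum <- 0.5
  eta <- if (n < 100) 50 else 200
  for (iter in seq_len(n_iter)) {
    pe <- if (iter <= 100L) p * exaggeration else p
    yd2 <- as.matrix(dist(y))^2
    num <- 1 / (1 + yd2)
    diag(num) <- 0
    q <- num / sum(num)
    q[q < .Machine$double.xmin] <- .Machine$double.xmin
    l <- (pe - q) * num
    grad <- 4 * (diag(rowSums(l)) - l) %*% y
    if (iter == 250L) momentum <- 0.8
    inc <- momentum * inc - eta * grad
    y <- y + inc
    y <- sweep(y, 2L, colMeans(y), "-")
  }
  y
}

#' Seeded 3D embedding of PC coordinates
#'
#' Embeds the kept principal components into 3D with exact t-SNE (the
#' Euclidean PC-space distances drive the affinities). Duplicate rows are
#' collapsed before embedding and mapped back to coincident points, so
#' identical inputs always receive identical coordinates. A
#' nearest-neighbour preservation diagnostic (fraction of each point's 5
#' PC-space nearest neighbours retained in 3D) is attached.
#'
#' @param pcs numeric matrix of PC scores.
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity; must satisfy
#'   `perplexity < (n_unique - 1) / 3`, where `n_unique` counts distinct
#'   rows. `NULL` (default) picks `min(30, (n_unique - 1) / 3)` capped
#'   below at 0.5.
#' @param n_iter gradient-descent iterations (default 1000).
#' @return n x 3 coordinate matrix with attribute `"nn_preservation"`.
#' @export
embed_3d <- function(pcs, seed = 1L, perplexity = NULL, n_iter = 1000L) {
  pcs <- as.matrix(pcs)
  key <- apply(pcs, 1L, paste, collapse = "\r")
  uniq <- !duplicated(key)
  ux <- pcs[uniq, , drop = FALSE]
  map <- match(key, key[uniq])
  nu <- nrow(ux)
  max_perp <- (nu - 1) / 3
  if (is.null(perplexity)) {
    perplexity <- max(0.5, min(30, max_perp * 0.99))
  } else if (perplexity >= max_perp) {
    abort_validation("perplexity ", perplexity, " needs at least ",
                     ceiling(3 * perplexity + 1), " distinct rows (have ",
                     nu, ")")
  }
  if (nu <= 3L) {
    # too few distinct profiles for a neighbour embedding: use the leading
    # PC coordinates directly, padded to 3D
    yu <- cbind(ux, matrix(0, nu, 3L))[, 1:3, drop = FALSE]
  } else {
    yu <- tsne_exact(ux, dims = 3L, perplexity = perplexity,
                     n_iter = n_iter, seed = seed)
  }
  y <- yu[map, , drop = FALSE]
  rownames(y) <- rownames(pcs)
  colnames(y) <- c("x", "y", "z")
  attr(y, "nn_preservation") <- nn_preservation(pcs, y, k = 5L)
  y
}

# fraction of each point's k nearest neighbours (in `a`) retained among its
# k nearest neighbours in `b`; mean over points with >= k+1 distinct others
nn_preservation <- function(a, b, k = 5L) {
  n <- nrow(a)
  if (n < k + 2L) return(NA_real_)
  da <- as.matrix(dist(a)); db <- as.matrix(dist(b))
  diag(da) <- Inf; diag(db) <- Inf
  mean(vapply(seq_len(n), function(i) {
    na <- order(da[i, ])[seq_len(k)]
    nb <- order(db[i, ])[seq_len(k)]
    length(intersect(na, nb)) / k
  }, numeric(1L)))
}

#' Convert 3D coordinates to hexadecimal RGB colours
#'
#' Each axis is min-max scaled to 0..255 and rounded half-up; the three
#' channels form `#RRGGBB`. A zero-range axis maps to channel 128; if all
#' points coincide every colour is mid-gray `#808080`.
#'
#' @param coords3d n x 3 numeric matrix.
#' @return Character vector of `#RRGGBB` strings (uppercase).
#' @export
coords_to_hex <- function(coords3d) {
  coords3d <- as.matrix(coords3d)
  stopifnot(ncol(coords3d) == 3L)
  channels <- apply(coords3d, 2L, function(v) {
    rng <- range(v)
    if (rng[1L] == rng[2L]) return(rep(128L, length(v)))
    as.integer(round_half_up(255 * (v - rng[1L]) / (rng[2L] - rng[1L])))
  })
  channels <- matrix(channels, ncol = 3L)
  out <- sprintf("#%02X%02X%02X", channels[, 1L], channels[, 2L],
                 channels[, 3L])
  names(out) <- rownames(coords3d)
  out
}

#' Colour enrichment results by found-entity similarity
#'
#' End-to-end palette: presence/absence matrix of found entities -> PCA
#' (first `n_pcs` components) -> seeded 3D embedding -> hex colours, so
#' results driven by overlapping gene sets receive similar colours and
#' identical sets receive identical colours.
#'
#' @param results input accepted by [build_found_entity_matrix()].
#' @param n_pcs principal components kept (default 20).
#' @param seed integer seed.
#' @param perplexity,n_iter passed to [embed_3d()].
#' @return data.frame: id, x, y, z, hex; `"nn_preservation"` attribute as
#'   diagnostic.
#' @export
palette_from_enrichment <- function(results, n_pcs = 20L, seed = 1L,
                                    perplexity = NULL, n_iter = 1000L) {
  m <- build_found_entity_matrix(results)
  pcs <- suppressWarnings(pca_embed(m, n_pcs = n_pcs))
  y <- embed_3d(pcs, seed = seed, perplexity = perplexity, n_iter = n_iter)
  hex <- coords_to_hex(y)
  out <- data.frame(id = rownames(m), x = y[, 1L], y = y[, 2L], z = y[, 3L],
                    hex = unname(hex), stringsAsFactors = FALSE)
  attr(out, "nn_preservation") <- attr(y, "nn_preservation")
  rownames(out) <- NULL
  out
}
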