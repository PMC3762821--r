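#' Solver options for the low-rank + sparse decompositions
#'
#' Collects the tunable constants shared by [rpca_alm()], [ladmap_rpca()]
#' and [godec()]. Sensible defaults follow standard inexact-ALM practice:
#' `lam = 1/sqrt(max(m, n))` (set at solve time from the matrix size when
#' left `NULL`), `mu0 = 1.25 / ||D||_2`, geometric penalty growth, and a
#' relative Frobenius stopping tolerance.
#'
#' @param lam positive sparsity weight for the l1 term; `NULL` means the
#'   size-adaptive default.
#' @param mu0 initial penalty; `NULL` means `1.25 / ||D||_2`.
#' @param rho penalty growth factor (>= 1).
#' @param mu_max_factor penalty cap as a multiple of `mu0`.
#' @param tol relative Frobenius stopping tolerance.
#' @param max_iter iteration cap.
#' @param r target rank (GoDec).
#' @param k target cardinality of the sparse part (GoDec); `NULL` means 5%
#'   of the entries.
#' @param q power-iteration count for the randomized low-rank step (GoDec).
#' @param seed random seed for the randomized projections.
#' @return a list of class `solver_options`.
#' @export
solver_options <- function(lam = NULL, mu0 = NULL, rho = 1.5,
                           mu_max_factor = 1e7, tol = 1e-7, max_iter = 500L,
                           r = 2L, k = NULL, q = 2L, seed = 0L) {
  if (!is.null(lam) && lam <= 0) stop("lam must be positive", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (rho < 1) stop("rho must be >= 1", call. = FALSE)
  if (r < 1) stop("r must be >= 1", call. = FALSE)
  if (!is.null(k) && k < 0) stop("k must be >= 0", call. = FALSE)
  structure(list(lam = lam, mu0 = mu0, rho = rho,
                 mu_max_factor = mu_max_factor, tol = tol,
                 max_iter = as.integer(max_iter), r = as.integer(r), k = k,
                 q = as.integer(q), seed = as.integer(seed)),
            class = "solver_options")
}

as_values_matrix <- function(D) {
  if (inherits(D, "data_matrix")) D$values
  else if (is.matrix(D)) D
  else stop("expected a matrix or data_matrix", call. = FALSE)
}

# Evaluate a function with a private RNG stream; the caller's RNG state is
# untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

frob <- function(X) sqrt(sum(X * X))

spectral_norm <- function(X) {
  if (all(X == 0)) return(0)
  max(svd(X, nu = 0L, nv = 0L)$d)
}

numerical_rank <- function(X, rtol = 1e-8) {
  d <- svd(X, nu = 0L, nv = 0L)$d
  if (!length(d) || d[1L] == 0) return(0L)
  sum(d > rtol * d[1L])
}

#' Elementwise soft thresholding (shrinkage)
#'
#' The proximal operator of `tau * ||.||_1`: each entry x is mapped to
#' `sign(x) * max(|x| - tau, 0)`. This solves the sparse-component
#' subproblem of the augmented Lagrangian iteration exactly.
#'
#' @param X numeric matrix (or vector).
#' @param tau nonnegative threshold.
#' @return shrunken matrix of the same shape.
#' @export
#' @examples
#' soft_threshold(c(3, -0.5), 1)  # 2, 0
soft_threshold <- function(X, tau) {
  if (tau < 0) stop("tau must be nonnegative", call. = FALSE)
  sign(X) * pmax(abs(X) - tau, 0)
}

#' Singular value thresholding
#'
#' The proximal operator of `tau * ||.||_*` (nuclear norm): computes the
#' singular value decomposition X = U diag(d) V' and soft-thresholds the
#' singular values. Solves the low-rank subproblem of the augmented
#' Lagrangian iteration exactly.
#'
#' @param X numeric matrix.
#' @param tau nonnegative threshold.
#' @return matrix of the same shape with shrunken spectrum. The number of
#'   retained singular values is attached as attribute `"rank"`.
#' @export
svd_shrink <- function(X, tau) {
  if (tau < 0) stop("tau must be nonnegative", call. = FALSE)
  s <- svd(X)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) {
    out <- matrix(0, nrow(X), ncol(X))
    attr(out, "rank") <- 0L
    return(out)
  }
  out <- s$u[, keep, drop = FALSE] %*%
    (d[keep] * t(s$v[, keep, drop = FALSE]))
  attr(out, "rank") <- sum(keep)
  out
}

new_decomposition <- function(low_rank, sparse, noise = NULL, model,
                              iterations, residual, converged,
                              height = NULL, width = NULL, mu_trace = NULL,
                              obj_trace = NULL) {
  structure(list(
    low_rank = low_rank, sparse = sparse, noise = noise, model = model,
    iterations = iterations, residual = residual, converged = converged,
    rank_used = numerical_rank(low_rank),
    card_used = sum(sparse != 0),
    height = height, width = width,
    mu_trace = mu_trace, obj_trace = obj_trace),
    class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("decomposition_result [%s]: %d x %d, rank %d, card %d, residual %.3g (%s after %d iter)\n",
              x$model, nrow(x$low_rank), ncol(x$low_rank), x$rank_used,
              x$card_used, x$residual,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Robust PCA by inexact augmented Lagrange multipliers
#'
#' Decomposes `D = A + E` with `A` low-rank and `E` sparse by minimizing
#' `||A||_* + lam * ||E||_1` subject to `D = A + E`. The augmented
#' Lagrangian is minimized by alternating exact proximal steps — elementwise
#' shrinkage for `E`, singular value thresholding for `A` — followed by a
#' multiplier update `Y <- Y + mu * (D - A - E)` and geometric growth of the
#' penalty `mu`.
#'
#' Under broad incoherence conditions this convex program exactly recovers a
#' low-rank matrix whose entries are corrupted in an unknown sparse pattern,
#' which is what makes it suitable for separating a shared anatomical
#' background from per-frame structures in a CT stack.
#'
#' @param D input matrix, `data_matrix` or plain numeric matrix.
#' @param opts a [solver_options()] list.
#' @return a `decomposition_result` with elements `low_rank` (A), `sparse`
#'   (E), diagnostics, and frame geometry when `D` was a `data_matrix`.
#' @export
rpca_alm <- function(D, opts = solver_options()) {
  geom <- if (inherits(D, "data_matrix")) D[c("height", "width")] else list(height = NULL, width = NULL)
  D <- as_values_matrix(D)
  if (!all(is.finite(D))) stop("input matrix contains non-finite values", call. = FALSE)
  m <- nrow(D); n <- ncol(D)
  lam <- if (is.null(opts$lam)) 1 / sqrt(max(m, n)) else opts$lam
  normD <- frob(D)
  if (normD == 0)
    return(new_decomposition(matrix(0, m, n), matrix(0, m, n), model = "rpca",
                             iterations = 0L, residual = 0, converged = TRUE,
                             height = geom$height, width = geom$width))
  sigma1 <- spectral_norm(D)
  # dual-feasible multiplier start (Lin et al. inexact ALM convention)
  Y <- D / max(sigma1, max(abs(D)) / lam)
  mu <- if (is.null(opts$mu0)) 1.25 / sigma1 else opts$mu0
  mu_max <- opts$mu_max_factor * mu
  A <- matrix(0, m, n); E <- matrix(0, m, n)
  converged <- FALSE; it <- 0L; res <- Inf
  while (it < opts$max_iter) {
    it <- it + 1L
    E <- soft_threshold(D - A + Y / mu, lam / mu)
    A <- svd_shrink(D - E + Y / mu, 1 / mu)
    R <- D - A - E
    Y <- Y + mu * R
    mu <- min(opts$rho * mu, mu_max)
    res <- frob(R) / normD
    if (res < opts$tol) { converged <- TRUE; break }
  }
  new_decomposition(A, E, model = "rpca", iterations = it, residual = res,
                    converged = converged,
                    height = geom$height, width = geom$width)
}

#' Robust PCA by the linearized alternating direction method with adaptive
#' penalty
#'
#' Solves the same convex program as [rpca_alm()] (so both return the same
#' decomposition up to solver tolerance) with an adaptive penalty schedule:
#' the penalty is only increased, by a fixed factor, on iterations where the
#' scaled change of the iterates falls below a threshold, and the iteration
#' stops when both the constraint residual and the relative iterate change
#' are small. For the plain two-block constraint `D = A + E` the linear
#' maps are identities, so the linearization constant is 1 and each
#' subproblem is again an exact proximal step.
#'
#' @inheritParams rpca_alm
#' @param rho0 penalty growth factor applied on "settled" iterations.
#' @param eps2 threshold on the scaled iterate change that gates penalty
#'   growth and (together with `opts$tol` on the residual) stopping.
#' @return a `decomposition_result` (model tag `"ladmap"`) whose `mu_trace`
#'   records the non-decreasing penalty sequence.
#' @export
ladmap_rpca <- function(D, opts = solver_options(), rho0 = 1.6, eps2 = 1e-4) {
  geom <- if (inherits(D, "data_matrix")) D[c("height", "width")] else list(height = NULL, width = NULL)
  D <- as_values_matrix(D)
  if (!all(is.finite(D))) stop("input matrix contains non-finite values", call. = FALSE)
  m <- nrow(D); n <- ncol(D)
  lam <- if (is.null(opts$lam)) 1 / sqrt(max(m, n)) else opts$lam
  normD <- frob(D)
  if (normD == 0)
    return(new_decomposition(matrix(0, m, n), matrix(0, m, n), model = "ladmap",
                             iterations = 1L, residual = 0, converged = TRUE,
                             height = geom$height, width = geom$width,
                             mu_trace = numeric()))
  sigma1 <- spectral_norm(D)
  Y <- D / max(sigma1, max(abs(D)) / lam)
  mu <- if (is.null(opts$mu0)) 1.25 / sigma1 else opts$mu0
  mu_max <- opts$mu_max_factor * mu
  A <- matrix(0, m, n); E <- matrix(0, m, n)
  max_iter <- max(opts$max_iter, 1000L)
  mu_trace <- numeric(0L)
  converged <- FALSE; it <- 0L; res <- Inf
  while (it < max_iter) {
    it <- it + 1L
    E_new <- soft_threshold(D - A + Y / mu, lam / mu)
    A_new <- svd_shrink(D - E_new + Y / mu, 1 / mu)
    R <- D - A_new - E_new
    Y <- Y + mu * R
    chg <- mu * max(frob(A_new - A), frob(E_new - E)) / normD
    A <- A_new; E <- E_new
    res <- frob(R) / normD
    mu_trace[it] <- mu
    if (res < opts$tol && chg < eps2) { converged <- TRUE; break }
    mu <- min(mu_max, if (chg < eps2) rho0 * mu else mu)
  }
  new_decomposition(A, E, model = "ladmap", iterations = it, residual = res,
                    converged = converged,
                    height = geom$height, width = geom$width,
                    mu_trace = mu_trace)
}

#' Rank-r approximation by bilateral random projections
#'
#' Randomized low-rank approximation: the column space of `X` is probed
#' with a Gaussian matrix (`Y1 = X A1`), refined by `q` alternating
#' projections through `X` and `X'` with QR re-orthogonalization at each
#' pass, and the approximation is the projection of `X` onto the resulting
#' r-dimensional basis. With a decaying spectrum the result is close to the
#' optimal rank-r truncation at a fraction of its cost, which is what makes
#' the GoDec iteration fast on tall stacked image matrices.
#'
#' @param X numeric matrix.
#' @param r target rank, `1 <= r <= min(dim(X))`.
#' @param q number of power refinements (>= 0).
#' @param seed RNG seed for the Gaussian probe; the global RNG state is not
#'   disturbed.
#' @param oversample extra probe columns beyond `r` (capped at
#'   `min(dim(X)) - r`); the sketch is truncated back to rank `r` through
#'   the SVD of the small projected matrix. Oversampling is what keeps the
#'   approximation accurate when the spectral gap at rank r is small.
#' @return a rank-<= r matrix of the same shape.
#' @export
brp_approx <- function(X, r, q = 2L, seed = 0L, oversample = 5L) {
  stopifnot(is.matrix(X))
  if (r < 1 || r > min(dim(X)))
    stop("r must lie in [1, min(dim(X))]", call. = FALSE)
  p <- min(as.integer(oversample), min(dim(X)) - r)
  A1 <- with_seed(seed, matrix(stats::rnorm(ncol(X) * (r + p)), ncol(X), r + p))
  brp_core(X, A1, q, r)$L
}

# Power-iteration core shared with godec(); `probe` (n x (r + p)) is the
# matrix the column sketch starts from — random for cold starts, the
# previous row basis padded with fresh random columns for warm starts.
# Returns the rank-r approximation L and its row basis V (n x r).
brp_core <- function(X, probe, q, r) {
  Q <- qr.Q(qr(X %*% probe))
  for (j in seq_len(q)) {
    Q2 <- qr.Q(qr(crossprod(X, Q)))   # row-space pass through X'
    Q <- qr.Q(qr(X %*% Q2))           # column-space pass through X
  }
  B <- crossprod(Q, X)                # (r+p) x n projected matrix
  sv <- svd(B)
  keep <- seq_len(min(r, length(sv$d)))
  L <- (Q %*% sv$u[, keep, drop = FALSE]) %*%
    (sv$d[keep] * t(sv$v[, keep, drop = FALSE]))
  list(L = L, V = sv$v[, keep, drop = FALSE])
}

#' GoDec: low-rank + sparse + noise decomposition
#'
#' Approximately decomposes `X = L + S + G` under hard constraints
#' `rank(L) <= r` and `card(S) <= k`, alternating two projections: `L` is
#' the bilateral-random-projection rank-r approximation of `X - S`, and `S`
#' keeps the k largest-magnitude entries of `X - L` (zeroing the rest).
#' What is left over, `G = X - L - S`, is returned as the noise component
#' — unlike the convex solvers, GoDec models dense noise explicitly, which
#' is why it is the recommended model for heavily noisy CT sequences.
#'
#' Ties at the k-th magnitude are broken by storage order (first kept), so
#' the iteration is deterministic given the seed. The low-rank step warm
#' starts from the basis of the previous iteration, making the squared
#' residual non-increasing across iterations in practice.
#'
#' @param X input matrix, `data_matrix` or plain numeric matrix.
#' @param opts a [solver_options()]; fields used are `r`, `k` (default 5%
#'   of entries), `q`, `seed`, `tol` (on the relative change of the squared
#'   residual; values below 1e-6 are raised to 1e-6 since the randomized
#'   subproblem is solved approximately), `max_iter`.
#' @return a `decomposition_result` with `low_rank`, `sparse`, `noise`, and
#'   an `obj_trace` of squared residuals per iteration.
#' @export
godec <- function(X, opts = solver_options()) {
  geom <- if (inherits(X, "data_matrix")) X[c("height", "width")] else list(height = NULL, width = NULL)
  X <- as_values_matrix(X)
  if (!all(is.finite(X))) stop("input matrix contains non-finite values", call. = FALSE)
  m <- nrow(X); n <- ncol(X)
  r <- opts$r
  if (r < 1 || r > min(m, n))
    stop("r must lie in [1, min(dim(X))]", call. = FALSE)
  k <- if (is.null(opts$k)) ceiling(0.05 * m * n) else as.integer(opts$k)
  tol <- max(opts$tol, 1e-6)
  max_iter <- min(opts$max_iter, 100L)
  normX2 <- sum(X * X)
  if (normX2 == 0)
    return(new_decomposition(matrix(0, m, n), matrix(0, m, n),
                             noise = matrix(0, m, n), model = "godec",
                             iterations = 0L, residual = 0, converged = TRUE,
                             height = geom$height, width = geom$width,
                             obj_trace = numeric()))
  p <- min(5L, min(m, n) - r)   # probe oversampling
  rng <- with_seed(opts$seed, {
    probe0 <- matrix(stats::rnorm(n * (r + p)), n, r + p)
    pads <- lapply(seq_len(max_iter), function(i)
      if (p > 0L) matrix(stats::rnorm(n * p), n, p) else NULL)
    list(probe0 = probe0, pads = pads)
  })
  probe <- rng$probe0
  S <- matrix(0, m, n)
  obj <- numeric(0L)
  e_prev <- Inf; converged <- FALSE; it <- 0L
  L <- matrix(0, m, n)
  while (it < max_iter) {
    it <- it + 1L
    Xc <- X - S
    fit <- brp_core(Xc, probe, opts$q, r)
    L <- fit$L
    # warm start: previous row basis, padded back to r+p with fresh probes
    probe <- cbind(fit$V, rng$pads[[it]])
    R <- X - L
    S <- matrix(0, m, n)
    if (k > 0L) {
      idx <- order(-abs(R))[seq_len(min(k, length(R)))]
      S[idx] <- R[idx]
    }
    e <- sum((R - S)^2)
    obj[it] <- e
    if (is.finite(e_prev) && abs(e_prev - e) <= tol * max(e_prev, .Machine$double.eps)) {
      converged <- TRUE
      e_prev <- e
      break
    }
    e_prev <- e
  }
  G <- X - L - S
  new_decomposition(L, S, noise = G, model = "godec", iterations = it,
                    residual = sqrt(sum(G * G)) / sqrt(normX2),
                    converged = converged,
                    height = geom$height, width = geom$width, obj_trace = obj)
}

#' Save or load a decomposition result as plain-text matrices plus JSON
#' diagnostics
#'
#' Matrices are written as gzip-compressed TSV; diagnostics (model,
#' iterations, residual, rank, cardinality, geometry) as `diagnostics.json`.
#'
#' @param res a `decomposition_result`.
#' @param dir target directory (created if needed).
#' @return `save_decomposition` invisibly returns `dir`;
#'   `load_decomposition` returns the reconstructed `decomposition_result`.
#' @export
save_decomposition <- function(res, dir) {
  stopifnot(inherits(res, "decomposition_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_mat <- function(M, name) {
    con <- gzfile(file.path(dir, paste0(name, ".tsv.gz")), "w")
    on.exit(close(con))
    utils::write.table(M, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  write_mat(res$low_rank, "low_rank")
  write_mat(res$sparse, "sparse")
  if (!is.null(res$noise)) write_mat(res$noise, "noise")
  diag <- res[c("model", "iterations", "residual", "converged", "rank_used",
                "card_used", "height", "width")]
  jsonlite::write_json(diag[!vapply(diag, is.null, logical(1L))],
                       file.path(dir, "diagnostics.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_decomposition
#' @export
load_decomposition <- function(dir) {
  read_mat <- function(name) {
    path <- file.path(dir, paste0(name, ".tsv.gz"))
    if (!file.exists(path)) return(NULL)
    as.matrix(utils::read.table(gzfile(path), sep = "\t"))
  }
  d <- jsonlite::read_json(file.path(dir, "diagnostics.json"), simplifyVector = TRUE)
  L <- unname(read_mat("low_rank")); S <- unname(read_mat("sparse"))
  G <- read_mat("noise"); if (!is.null(G)) G <- unname(G)
  dimnames(L) <- dimnames(S) <- NULL
  new_decomposition(L, S, noise = G, model = d$model,
                    iterations = d$iterations, residual = d$residual,
                    converged = d$converged,
                    height = d$height, width = d$width)
}
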