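# Non-negative matrix factorization engine: Frobenius loss, multiplicative
# updates, non-negative double-SVD initialization with random restarts.
# Written for mutation-spectrum matrices (dense, small) where a best-of-
# restarts deterministic factorization is what matters.

#' Evaluate code under a temporary RNG state
#'
#' Seeds the R RNG, runs `code`, and restores the caller's RNG state so a
#' seeded computation never perturbs the surrounding random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Non-negative double SVD initialization (Boutsidis & Gallopoulos).
nndsvd_init <- function(V, k) {
  sv <- svd(V, nu = k, nv = k)
  n <- nrow(V); m <- ncol(V)
  W <- matrix(0, n, k); H <- matrix(0, k, m)
  W[, 1L] <- sqrt(sv$d[1L]) * abs(sv$u[, 1L])
  H[1L, ] <- sqrt(sv$d[1L]) * abs(sv$v[, 1L])
  if (k > 1L) for (j in 2:k) {
    x <- sv$u[, j]; y <- sv$v[, j]
    xp <- pmax(x, 0); xn <- pmax(-x, 0)
    yp <- pmax(y, 0); yn <- pmax(-y, 0)
    xpn <- sqrt(sum(xp^2)); xnn <- sqrt(sum(xn^2))
    ypn <- sqrt(sum(yp^2)); ynn <- sqrt(sum(yn^2))
    mp <- xpn * ypn; mn <- xnn * ynn
    if (mp >= mn && mp > 0) {
      W[, j] <- sqrt(sv$d[j] * mp) * xp / xpn
      H[j, ] <- sqrt(sv$d[j] * mp) * yp / ypn
    } else if (mn > 0) {
      W[, j] <- sqrt(sv$d[j] * mn) * xn / xnn
      H[j, ] <- sqrt(sv$d[j] * mn) * yn / ynn
    }
  }
  eps <- mean(V) * 1e-4
  W[W <= 0] <- eps
  H[H <= 0] <- eps
  list(W = W, H = H)
}

# One multiplicative-update run from a given initialization.
nmf_run <- function(V, W, H, max_iter, tol) {
  eps <- .Machine$double.eps
  rss_prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
    W <- W * (tcrossprod(V, H) / (W %*% tcrossprod(H) + eps))
    if (it %% 10L == 0L || it == max_iter) {
      rss <- sum((V - W %*% H)^2)
      if (rss <= 1e-6 * sum(V^2)) {  # essentially exact fit
        converged <- TRUE
        rss_prev <- rss
        break
      }
      if (is.finite(rss_prev) &&
          abs(rss_prev - rss) <= tol * max(rss_prev, eps)) {
        converged <- TRUE
        rss_prev <- rss
        break
      }
      rss_prev <- rss
    }
  }
  list(W = W, H = H, rss = sum((V - W %*% H)^2), converged = converged,
       iterations = it)
}

#' Low-level non-negative matrix factorization
#'
#' Factors a non-negative matrix `V` (n x m) as `W %*% H` with Frobenius
#' loss and multiplicative updates. The first restart starts from a
#' non-negative double-SVD initialization; further restarts perturb it with
#' random multiplicative noise. The restart with the lowest residual sum of
#' squares is returned. Deterministic for a fixed `seed`.
#'
#' @param V non-negative numeric matrix.
#' @param k factorization rank.
#' @param seed integer seed controlling the restart noise.
#' @param restarts number of initializations to try (>= 1).
#' @param max_iter maximum multiplicative-update iterations per restart.
#' @param tol relative RSS change below which a run is declared converged.
#' @return list with `W`, `H`, `rss`, `converged`, `iterations`.
#' @keywords internal
nmf_fit <- function(V, k, seed = 1L, restarts = 5L, max_iter = 5000L,
                    tol = 1e-6) {
  stopifnot(all(V >= 0), k >= 1L, restarts >= 1L)
  init0 <- nndsvd_init(V, k)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- if (r == 1L) init0 else {
        list(W = init0$W * matrix(stats::runif(length(init0$W), 0.5, 1.5),
                                  nrow(init0$W)),
             H = init0$H * matrix(stats::runif(length(init0$H), 0.5, 1.5),
                                  nrow(init0$H)))
      }
      fit <- nmf_run(V, init$W, init$H, max_iter = max_iter, tol = tol)
      if (is.null(best) || fit$rss < best$rss) best <- fit
    }
  })
  if (!best$converged)
    warning("NMF did not converge within ", max_iter,
            " iterations (final RSS ", signif(best$rss, 6), ")")
  best
}
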