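#' Genotype principal component analysis
#'
#' Standard genotype PCA: each variant is centered by its mean dosage `2p`
#' and scaled by the binomial standard deviation `sqrt(2 p (1 - p))` at the
#' observed alternate-allele frequency; missing dosages are mean-imputed
#' (zero after centering). Scores come from the singular value decomposition
#' of the standardized matrix.
#'
#' @param gm a [genotype_matrix()] with at least 2 samples and 1 polymorphic
#'   variant.
#' @param n_components number of components to return (default 10, capped at
#'   the matrix rank bound).
#' @return An object of class `pca_result`: `coordinates` (samples x
#'   components), `explained_var` (per-component fraction of total variance,
#'   non-increasing), `loadings` (variant weights) and `kept` (indices of the
#'   polymorphic variants used).
#' @export
genotype_pca <- function(gm, n_components = 10) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(gm$samples) < 2) stop("need >= 2 samples")
  p <- allele_freq(gm)
  kept <- which(!is.na(p) & p > 0 & p < 1)
  if (!length(kept)) stop("all variants monomorphic")
  X <- gm$dosage[, kept, drop = FALSE]
  p <- p[kept]
  X <- sweep(X, 2, 2 * p)
  X[is.na(X)] <- 0
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  k <- min(n_components, dim(X))
  sv <- svd(X)
  tot <- sum(sv$d^2)
  expl <- if (tot > 0) sv$d^2 / tot else rep(0, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      nrow = k)
  rownames(scores) <- gm$samples
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(coordinates = scores,
                 explained_var = expl[seq_len(k)],
                 loadings = sv$v[, seq_len(k), drop = FALSE],
                 kept = kept),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("genotype PCA: %d samples, %d components (PC1 %.1f%% of variance)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$explained_var[1]))
  invisible(x)
}

#' Least-squares ancestry coefficients (sNMF-style)
#'
#' Estimates per-sample ancestry proportions `Q` (rows on the K-simplex) and
#' ancestral allele frequencies `F` (entries in `[0, 1]`) by minimizing
#' `|| X/2 - Q F ||^2` over the constraint sets, where `X` is the dosage
#' matrix with missing entries mean-imputed. Alternating projected
#' least-squares updates: `F` is solved per variant and clamped to `[0, 1]`;
#' `Q` is solved per sample, clamped at zero and renormalized to unit row
#' sum. Iterates are accepted only while the loss is non-increasing.
#'
#' The least-squares factorization is only identified up to an invertible
#' remix of the components, and with finite data the fitted `F` brackets
#' the sample cloud so unadmixed samples land slightly inside the simplex.
#' Under the standard anchor assumption -- each ancestral component has at
#' least one (near-)unadmixed sample -- the vertex member of the solution
#' class is recovered by remixing with the inverse of the `K` most extreme
#' `Q` rows (`anchor = TRUE`), leaving the fit `Q F` unchanged.
#'
#' The least-squares objective is invariant under invertible remixing of the
#' components, so the first restart is anchored at a k-means clustering of
#' the samples (one-hot `Q`, cluster-mean `F`), which selects the vertex
#' member of the solution class; the remaining restarts are random and
#' replace it only on a strictly better loss.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of ancestral components (`1 <= K <= n samples`).
#' @param seed RNG seed for the restarts.
#' @param n_restarts number of random restarts (default 5).
#' @param tol relative loss-change convergence tolerance (default 1e-6).
#' @param max_iter maximum alternating iterations per restart (default 300).
#' @param anchor apply anchor (vertex) normalization to the returned
#'   factors (default `TRUE`).
#' @return An object of class `ancestry_result`: `K`, `Q` (samples x K), `F`
#'   (K x variants), `loss`, `loss_trace` and `converged` (with a warning on
#'   non-convergence).
#' @export
ancestry_coefficients <- function(gm, K, seed = 1, n_restarts = 5,
                                  tol = 1e-6, max_iter = 300,
                                  anchor = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"), K >= 1,
            K <= length(gm$samples))
  X <- gm$dosage / 2
  cm <- colMeans(X, na.rm = TRUE)
  miss <- which(is.na(X), arr.ind = TRUE)
  if (nrow(miss)) X[miss] <- cm[miss[, 2]]
  n <- nrow(X); V <- ncol(X)
  if (K == 1) {
    Q <- matrix(1, n, 1, dimnames = list(gm$samples, NULL))
    F_ <- matrix(colMeans(X), 1, V)
    loss <- sum((X - Q %*% F_)^2)
    return(structure(list(K = 1L, Q = Q, F = F_, loss = loss,
                          loss_trace = loss, converged = TRUE),
                     class = "ancestry_result"))
  }
  set.seed(seed)
  best <- NULL
  eps <- 1e-9
  for (restart in seq_len(n_restarts)) {
    if (restart == 1) {
      km <- tryCatch(kmeans(X, centers = K, nstart = 5), error = function(e) NULL)
      if (!is.null(km)) {
        Q <- matrix(0, n, K)
        Q[cbind(seq_len(n), km$cluster)] <- 1
        F_ <- km$centers
        dimnames(F_) <- NULL
      } else {
        Q <- matrix(rexp(n * K), n, K)
        Q <- Q / rowSums(Q)
        F_ <- matrix(runif(K * V), K, V)
      }
    } else {
      Q <- matrix(rexp(n * K), n, K)
      Q <- Q / rowSums(Q)
      F_ <- matrix(runif(K * V), K, V)
    }
    loss <- sum((X - Q %*% F_)^2)
    trace <- loss
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      F_new <- solve(crossprod(Q) + eps * diag(K), crossprod(Q, X))
      F_new[F_new < 0] <- 0; F_new[F_new > 1] <- 1
      Q_new <- t(solve(tcrossprod(F_new) + eps * diag(K), F_new %*% t(X)))
      Q_new[Q_new < 0] <- 0
      zero <- rowSums(Q_new) == 0
      Q_new[zero, ] <- 1
      Q_new <- Q_new / rowSums(Q_new)
      loss_new <- sum((X - Q_new %*% F_new)^2)
      if (loss_new > loss + 1e-12) { # reject uphill step, keep previous
        converged <- TRUE
        break
      }
      accepted_rel <- (loss - loss_new) / max(loss, .Machine$double.eps)
      Q <- Q_new; F_ <- F_new; loss <- loss_new
      trace <- c(trace, loss)
      if (accepted_rel < tol) { converged <- TRUE; break }
    }
    if (is.null(best) || loss < best$loss * (1 - 1e-6))
      best <- list(Q = Q, F = F_, loss = loss, trace = trace,
                   converged = converged)
  }
  if (!best$converged)
    warning("ancestry estimation did not converge; returning best iterate")
  if (anchor) {
    cal <- anchor_calibrate(best$Q, best$F)
    best$Q <- cal$Q; best$F <- cal$F
  }
  rownames(best$Q) <- gm$samples
  structure(list(K = as.integer(K), Q = best$Q, F = best$F, loss = best$loss,
                 loss_trace = best$trace, converged = best$converged),
            class = "ancestry_result")
}

# remix (Q, F) -> (Q A^-1, A F) with A the K most component-extreme Q rows,
# so those anchor samples sit exactly on the simplex vertices; the fitted
# matrix Q F is unchanged up to the final feasibility clamp
anchor_calibrate <- function(Q, F_) {
  K <- ncol(Q)
  anchors <- unique(vapply(seq_len(K), function(k) which.max(Q[, k]),
                           integer(1)))
  if (length(anchors) < K) return(list(Q = Q, F = F_))
  A <- Q[anchors, , drop = FALSE]
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) return(list(Q = Q, F = F_))
  Qc <- Q %*% Ainv
  Qc[Qc < 0] <- 0
  zero <- rowSums(Qc) == 0
  Qc[zero, ] <- 1
  Qc <- Qc / rowSums(Qc)
  Fc <- A %*% F_
  Fc[Fc < 0] <- 0; Fc[Fc > 1] <- 1
  list(Q = Qc, F = Fc)
}

#' @export
print.ancestry_result <- function(x, ...) {
  cat(sprintf("ancestry: K = %d, %d samples, loss = %.4g (%s)\n",
              x$K, nrow(x$Q), x$loss,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Flag putative F1 hybrids from ancestry coefficients
#'
#' With K = 2 ancestral components, a sample is flagged as a hybrid iff both
#' of its ancestry coefficients fall inside `[lo, hi]` -- i.e. it carries
#' almost the same proportion of ancestry from each source population.
#'
#' @param ancestry an `ancestry_result` with `K = 2`.
#' @param lo,hi the hybrid interval (defaults 0.35 and 0.65).
#' @return Named logical vector over samples.
#' @export
hybrid_flag <- function(ancestry, lo = 0.35, hi = 0.65) {
  stopifnot(inherits(ancestry, "ancestry_result"))
  if (ancestry$K != 2) stop("hybrid_flag requires K = 2")
  q1 <- ancestry$Q[, 1]
  q2 <- ancestry$Q[, 2]
  setNames(q1 >= lo & q1 <= hi & q2 >= lo & q2 <= hi, rownames(ancestry$Q))
}
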