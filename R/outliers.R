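# Distance-Distance analysis of gene characteristics: classical Mahalanobis
# distance, Stahel-Donoho robust distance, and chi-square-cutoff outlier
# classification.

# run expr with a deterministic RNG state, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Column-standardize a feature matrix
#'
#' Centers every column to mean 0 and scales to sample standard deviation 1,
#' as the Distance-Distance analysis requires (the features span orders of
#' magnitude, e.g. coding span in kb vs. CAI in (0,1]).
#'
#' @param X Numeric matrix (rows = genes).
#' @return The standardized matrix; zero-variance columns are left centered
#'   and flagged via the `zero_variance` attribute.
#' @export
standardize_features <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  zv <- sdv == 0
  sdv[zv] <- 1
  out <- sweep(sweep(X, 2L, ctr), 2L, sdv, "/")
  attr(out, "zero_variance") <- zv
  out
}

#' Classical Mahalanobis distances
#'
#' Distance of each row from the column-mean centroid under the sample
#' covariance.  A numerically singular covariance is ridged by
#' `1e-8 * trace(S)/p` on the diagonal and the result flagged.
#'
#' @param X Numeric matrix with more rows than columns.
#' @return Vector of distances (attribute `ridged` when regularized).
#' @export
mahalanobis_distance <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than variables (n > p)")
  S <- cov(X)
  ridged <- FALSE
  d2 <- tryCatch(stats::mahalanobis(X, colMeans(X), S),
                 error = function(e) NULL)
  if (is.null(d2) || anyNA(d2)) {
    S <- S + diag(1e-8 * sum(diag(S)) / p, p)
    d2 <- stats::mahalanobis(X, colMeans(X), S)
    ridged <- TRUE
  }
  structure(sqrt(pmax(d2, 0)), ridged = ridged)
}

#' Stahel-Donoho robust location, scatter, and distances
#'
#' Projection-pursuit outlyingness: each observation's outlyingness is its
#' maximal standardized deviation |x'd - median(X d)| / MAD(X d) over a set
#' of directions (all p coordinate axes plus normalized differences of
#' random row pairs, seeded).  Observations are weighted by
#' w(r) = min(1, (c/r)^2) with c = sqrt(qchisq(0.95, p)); the weighted mean
#' and weighted covariance are the robust location/scatter, and the robust
#' distance is the Mahalanobis distance under these estimates.
#'
#' @param X Numeric matrix, n > 2p rows.
#' @param n_directions Number of random-pair directions (default 250*p).
#' @param seed Integer seed making the direction sample reproducible.
#' @return List with `location`, `scatter`, `rd`, `outlyingness`, `weights`.
#' @export
stahel_donoho <- function(X, n_directions = 250L * ncol(X), seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= 2L * p) stop("Stahel-Donoho needs n > 2p")
  # pairs are drawn from lexicographically sorted rows so the direction set
  # (and hence rd) is invariant to the row order of X for a fixed seed
  Xs <- X[do.call(order, as.data.frame(X)), , drop = FALSE]
  D <- .with_seed(seed, {
    i <- sample.int(n, n_directions, replace = TRUE)
    j <- sample.int(n, n_directions, replace = TRUE)
    V <- Xs[i, , drop = FALSE] - Xs[j, , drop = FALSE]
    nrm <- sqrt(rowSums(V^2))
    keep <- nrm > 0
    V <- V[keep, , drop = FALSE] / nrm[keep]
    rbind(diag(p), V)
  })
  Z <- X %*% t(D)                      # n x n_dir projections
  meds <- apply(Z, 2L, median)
  mads <- apply(Z, 2L, mad)            # 1.4826 consistency factor (default)
  ok <- mads > 0
  if (!any(ok)) stop("all projection directions have zero MAD")
  Zc <- abs(sweep(Z[, ok, drop = FALSE], 2L, meds[ok]))
  Zc <- sweep(Zc, 2L, mads[ok], "/")
  r <- apply(Zc, 1L, max)
  cc <- sqrt(qchisq(0.95, p))
  w <- pmin(1, (cc / r)^2)
  loc <- colSums(X * w) / sum(w)
  Xc <- sweep(X, 2L, loc)
  scatter <- crossprod(Xc * sqrt(w)) / (sum(w) - 1)
  rd <- sqrt(pmax(stats::mahalanobis(X, loc, scatter), 0))
  list(location = loc, scatter = scatter, rd = rd,
       outlyingness = r, weights = w)
}

#' Distance-Distance outlier classification
#'
#' Flags observations whose classical (MD) or robust (RD) Mahalanobis
#' distance exceeds the square root of the `quantile` quantile of the
#' chi-square distribution with `p` degrees of freedom (4.19 for p = 8,
#' quantile 0.975).  Quadrants follow the usual Distance-Distance plot
#' reading: RD-only outliers are those masked for the classical estimate.
#'
#' @param md,rd Equal-length distance vectors.
#' @param p Dimension (degrees of freedom), default 8.
#' @param quantile Chi-square quantile, default 0.975.
#' @return A `dd_result` data.frame with md, rd, outlier flags and quadrant,
#'   plus a `cutoff` attribute.
#' @export
dd_classify <- function(md, rd, p = 8L, quantile = 0.975) {
  if (length(md) != length(rd)) stop("md and rd lengths differ")
  cutoff <- sqrt(qchisq(quantile, df = p))
  omd <- md > cutoff
  ord <- rd > cutoff
  quadrant <- ifelse(omd & ord, "both",
              ifelse(ord, "rd_only",
              ifelse(omd, "md_only", "regular")))
  structure(data.frame(md = md, rd = rd, outlier_md = omd,
                       outlier_rd = ord, quadrant = quadrant,
                       stringsAsFactors = FALSE),
            cutoff = cutoff, class = c("dd_result", "data.frame"))
}

#' Full Distance-Distance analysis of a gene feature matrix
#'
#' Standardizes the eight gene characteristics, computes classical and
#' Stahel-Donoho robust Mahalanobis distances, and applies the chi-square
#' cutoff.
#'
#' @param X Numeric feature matrix (genes x 8 characteristics).
#' @param quantile Chi-square quantile for the cutoff (default 0.975).
#' @param n_directions,seed Passed to [stahel_donoho()].
#' @return A `dd_result` (see [dd_classify()]) with row names from `X`.
#' @export
dd_analysis <- function(X, quantile = 0.975, n_directions = 250L * ncol(X),
                        seed = 1L) {
  Z <- standardize_features(X)
  md <- mahalanobis_distance(Z)
  sd_fit <- stahel_donoho(Z, n_directions = n_directions, seed = seed)
  res <- dd_classify(as.numeric(md), sd_fit$rd, p = ncol(Z),
                     quantile = quantile)
  rownames(res) <- rownames(X)
  res
}
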