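#' Polychoric correlation and the asset index
#'
#' Household wealth is summarized by the first principal component of the
#' polychoric correlation matrix of ordinal asset-ownership items, the
#' standard construction for asset indices when items are ordinal rather than
#' continuous. Polychoric correlations are estimated by the two-step method:
#' category thresholds from the marginal frequencies via the inverse normal,
#' then the latent correlation by maximizing the bivariate-normal cell
#' likelihood.
#'
#' @name asset_index_methods
NULL

# Bivariate standard normal CDF P(X <= h, Y <= k) at correlation rho, via the
# one-dimensional reduction integral of phi(x) * Phi((k - rho x)/sqrt(1-rho^2))
# on fixed Gauss-Legendre nodes (vectorized over (h, k) pairs).
bvn_cdf <- function(h, k, rho) {
  n <- max(length(h), length(k))
  h <- rep_len(h, n); k <- rep_len(k, n)
  out <- numeric(n)
  lo <- -8.5
  hi <- pmin(h, 8.5)
  s <- sqrt(1 - rho^2)
  gl <- gauss_legendre_64()
  for (i in seq_len(n)) {
    if (h[i] <= lo) { out[i] <- 0; next }
    if (h[i] >= 8.5 && k[i] >= 8.5) { out[i] <- 1; next }
    if (k[i] >= 8.5) { out[i] <- stats::pnorm(h[i]); next }
    if (k[i] <= lo) { out[i] <- 0; next }
    mid <- (hi[i] + lo) / 2; half <- (hi[i] - lo) / 2
    x <- mid + half * gl$nodes
    out[i] <- half * sum(gl$weights * stats::dnorm(x) *
                           stats::pnorm((k[i] - rho * x) / s))
  }
  out
}

gauss_legendre_64 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gl <- pracma::gaussLegendre(64, -1, 1)
      cache <<- list(nodes = gl$x, weights = gl$w)
    }
    cache
  }
})

# Rectangle probabilities of the bivariate normal over the threshold grids
# tx, ty (each including -Inf and +Inf endpoints implicitly via c(-Inf, t, Inf))
bvn_cell_probs <- function(tx, ty, rho) {
  gx <- c(-Inf, tx, Inf); gy <- c(-Inf, ty, Inf)
  K <- length(gx); L <- length(gy)
  grid <- outer(gx, gy, function(a, b) bvn_cdf(a, b, rho))
  p <- grid[-1, -1, drop = FALSE] - grid[-K, -1, drop = FALSE] -
    grid[-1, -L, drop = FALSE] + grid[-K, -L, drop = FALSE]
  pmax(p, 1e-12)
}

#' Two-step polychoric correlation for a pair of ordinal variables
#'
#' @param x,y Ordinal vectors (integer codes or ordered factors); at least two
#'   observed categories each.
#' @return List with `rho` (ML estimate given the marginal thresholds),
#'   `thresholds_x`, `thresholds_y`, and the maximized `loglik`.
#' @export
polychoric_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  tab <- table(x[ok], y[ok])
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("polychoric_rho: both variables need >= 2 observed categories")
  tx <- stats::qnorm(cumsum(rowSums(tab))[-nrow(tab)] / sum(tab))
  ty <- stats::qnorm(cumsum(colSums(tab))[-ncol(tab)] / sum(tab))
  nll <- function(r) -sum(tab * log(bvn_cell_probs(tx, ty, r)))
  opt <- stats::optimize(nll, interval = c(-0.9999, 0.9999), tol = 1e-6)
  list(rho = opt$minimum, thresholds_x = unname(tx), thresholds_y = unname(ty),
       loglik = -opt$objective)
}

#' Polychoric correlation matrix
#'
#' @param items Data frame or matrix of ordinal items (columns).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
polychoric_matrix <- function(items) {
  items <- as.data.frame(items)
  J <- ncol(items)
  R <- diag(1, J)
  dimnames(R) <- list(names(items), names(items))
  for (a in seq_len(J - 1L)) for (b in seq.int(a + 1L, J)) {
    R[a, b] <- R[b, a] <- polychoric_rho(items[[a]], items[[b]])$rho
  }
  R
}

#' Polychoric principal-component asset index
#'
#' Estimates the polychoric correlation matrix of the asset items, extracts
#' its first eigenvector, scores participants with normal-score category
#' quantifications, and marks deprivation at `score <= mean - threshold_sd*SD`
#' of the scores. The component sign is fixed so that asset ownership (higher
#' item categories) loads positively, making higher scores mean more assets.
#'
#' A non-positive-definite polychoric matrix is repaired by clipping its
#' eigenvalues at a small floor (with a warning) before extraction.
#'
#' @param items Data frame or matrix of ordinal asset items, `>= 2` columns,
#'   each with `>= 2` observed categories. Higher categories = more assets.
#' @param threshold_sd SD multiplier for the deprivation cut (default 1).
#' @return List with `scores`, `deprived` (0/1), `loadings` (first
#'   eigenvector), `rho` (polychoric matrix), `eigenvalues`, and
#'   `var_explained` (share of total variance on the first component).
#' @export
asset_index <- function(items, threshold_sd = 1) {
  items <- as.data.frame(items)
  if (ncol(items) < 2L) stop("asset_index: need >= 2 items")
  R <- pd_repair(polychoric_matrix(items))
  ev <- eigen(R, symmetric = TRUE)
  v <- ev$vectors[, 1L]

  # normal-score quantification of each item's categories, then weighted sum
  quant <- lapply(items, normal_score_quantification)
  S <- vapply(seq_along(items), function(j) {
    q <- quant[[j]]
    q$value[match(as.character(items[[j]]), q$category)]
  }, numeric(nrow(items)))
  if (is.null(dim(S))) S <- matrix(S, nrow = nrow(items))

  # orient so ownership loads positively: score should increase with raw items
  scores <- as.vector(S %*% v)
  ranked <- rowSums(vapply(items, function(col) as.numeric(as.factor(col)),
                           numeric(nrow(items))))
  if (stats::cov(scores, ranked) < 0) { v <- -v; scores <- -scores }

  list(scores = scores,
       deprived = threshold_deficit(scores, threshold_sd, name = "asset_index"),
       loadings = stats::setNames(v, colnames(R)),
       rho = R, eigenvalues = ev$values,
       var_explained = ev$values[1L] / sum(ev$values))
}

# Repair a non-positive-definite correlation matrix by clipping eigenvalues
# at a small floor and rescaling to unit diagonal; warns when repair fires.
pd_repair <- function(R, floor = 1e-8) {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) >= floor) return(R)
  warning("polychoric correlation matrix not positive definite; ",
          "eigenvalues clipped at ", format(floor))
  R2 <- ev$vectors %*% diag(pmax(ev$values, floor)) %*% t(ev$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / outer(d, d)
  dimnames(R2) <- dimnames(R)
  R2
}

# E[Z | category] under the marginal normal discretization of one ordinal item
normal_score_quantification <- function(x) {
  tab <- table(x[!is.na(x)])
  if (length(tab) < 2L) stop("asset item has < 2 observed categories")
  cum <- cumsum(tab) / sum(tab)
  hi <- stats::qnorm(cum)
  lo <- c(-Inf, hi[-length(hi)])
  val <- (stats::dnorm(lo) - stats::dnorm(hi)) / (stats::pnorm(hi) - stats::pnorm(lo))
  data.frame(category = names(tab), value = as.numeric(val),
             stringsAsFactors = FALSE)
}
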