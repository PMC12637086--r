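## Simplex/archetype analysis: principal-convex-hull fitting, the t-ratio
## statistic with its shuffled-loadings permutation test, archetype
## discretization and enrichment, and the continuum-vs-cluster diagnostic.

## Euclidean projection of every column of M onto the probability simplex
.proj_cols_simplex <- function(M) {
  k <- nrow(M); m <- ncol(M)
  o <- order(col(M), M, method = "radix",
             decreasing = c(FALSE, TRUE))
  Ms <- matrix(M[o], k, m)
  cum <- Ms
  if (k > 1) for (i in 2:k) cum[i, ] <- cum[i - 1L, ] + Ms[i, ]
  j <- matrix(seq_len(k), k, m)
  cond <- Ms > (cum - 1) / j
  rho <- colSums(cond)                     # conditions are monotone in j
  theta <- (cum[cbind(rho, seq_len(m))] - 1) / rho
  pmax(M - rep(theta, each = k), 0)
}

## furthest-first traversal: k spread-out starting points
.furthest_first <- function(x, k, first) {
  n <- nrow(x)
  sel <- integer(k); sel[1] <- first
  d2 <- rowSums(sweep(x, 2, x[first, ])^2)
  if (k > 1) for (i in 2:k) {
    sel[i] <- which.max(d2)
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[sel[i], ])^2))
  }
  sel
}

## Principal-convex-hull (archetypal analysis) by alternating projected
## gradient with backtracking: X ~ X C S, columns of C and S on the simplex.
## X is d x n. Returns C (n x k), S (k x n), rss trace.
.pcha <- function(X, k, init, maxiter = 250, tol = 1e-8) {
  n <- ncol(X)
  C <- matrix(0, n, k); C[cbind(init, seq_len(k))] <- 1
  A <- X %*% C                       # d x k archetypes
  AtA <- crossprod(A)
  S <- .proj_cols_simplex(matrix(1 / k + stats::rnorm(k * n, 0, 0.01), k, n))
  ssX <- sum(X^2)
  rss <- function(S, A) ssX - 2 * sum((crossprod(X, A)) * t(S)) +
    sum(crossprod(A) * tcrossprod(S))
  f <- rss(S, A)
  mu_s <- 1; mu_c <- 1
  trace <- numeric(0)
  for (it in seq_len(maxiter)) {
    f_old <- f
    ## --- S update (projected gradient, backtracking)
    E <- A %*% S - X
    gS <- crossprod(A, E)
    for (b in 1:12) {
      S1 <- .proj_cols_simplex(S - mu_s * gS)
      f1 <- rss(S1, A)
      if (f1 <= f + 1e-12) { S <- S1; f <- f1; mu_s <- mu_s * 1.2; break }
      mu_s <- mu_s / 2
    }
    ## --- C update
    E <- A %*% S - X
    gC <- crossprod(X, E %*% t(S))
    for (b in 1:12) {
      C1 <- .proj_cols_simplex(C - mu_c * gC)
      A1 <- X %*% C1
      f1 <- rss(S, A1)
      if (f1 <= f + 1e-12) { C <- C1; A <- A1; f <- f1; mu_c <- mu_c * 1.2; break }
      mu_c <- mu_c / 2
    }
    trace <- c(trace, f)
    if (f_old - f <= tol * max(f_old, .Machine$double.eps)) break
  }
  list(C = C, S = S, A = A, rss = f, trace = trace)
}

## soft minimum-volume simplex: log-volume plus a linear hinge penalty on
## negative barycentric coordinates (violating points), optimized by BFGS
## with analytic (sub)gradients. V is the (d+1) x d vertex matrix; the
## hinge weight is normalized per cell so the volume/violation balance is
## sample-size free.
.mves_objective <- function(par, X1, d, lam_n) {
  k <- d + 1L
  V <- matrix(par, k, d)
  M <- sweep(V[-1, , drop = FALSE], 2, V[1, ])
  dt <- det(M)
  if (abs(dt) < 1e-300) return(1e10)
  E <- rbind(rep(1, k), t(V))              # (d+1) x (d+1)
  Einv <- tryCatch(solve(E), error = function(e) NULL)
  if (is.null(Einv)) return(1e10)
  B <- X1 %*% t(Einv)                      # n x k barycentric coords
  log(abs(dt)) + lam_n * sum(pmax(-B, 0))
}

.mves_gradient <- function(par, X1, d, lam_n) {
  k <- d + 1L
  V <- matrix(par, k, d)
  M <- sweep(V[-1, , drop = FALSE], 2, V[1, ])
  E <- rbind(rep(1, k), t(V))
  Einv <- solve(E)
  B <- X1 %*% t(Einv)
  ## d log|det M| / dV
  G <- t(solve(M))                         # d x d, rows follow M's rows
  gv <- matrix(0, k, d)
  gv[-1, ] <- G
  gv[1, ] <- -colSums(G)
  ## hinge subgradient: dh/dv_m = sum_i B_im * (1[b_i < 0] . Einv[, -1])
  Q <- (B < 0) %*% Einv[, -1, drop = FALSE]   # n x d
  gv <- gv + lam_n * crossprod(B, Q)
  as.vector(gv)
}

#' Fit a simplex (archetypes) to cells in PC space
#'
#' For \code{n_archetypes = d + 1} (the study's case: 4 archetypes in 3
#' PCs) the fitter finds a soft minimum-volume enclosing simplex, in the
#' SISAL/MVSA family: starting from furthest-point extreme cells inflated
#' to enclose the data, it minimizes log simplex volume plus a quadratic
#' hinge penalty on negative barycentric coordinates, so a few
#' noise-displaced cells may fall slightly outside rather than dragging
#' the vertices outward. If afterwards full enclosure needs only a
#' marginal homothetic inflation (below \code{snap_tol}), the simplex is
#' snapped to it (exact in the noiseless case). Cell weights are the
#' barycentric coordinates, clipped at zero and renormalized.
#'
#' For \code{n_archetypes != d + 1} a principal-convex-hull (archetypal
#' analysis) alternating projected-gradient fit is used instead, with
#' archetypes constrained to the data hull.
#'
#' @param scores cells x d matrix of PC scores; the simplex is fitted in
#'   these d dimensions.
#' @param n_archetypes number of archetypes (default d + 1).
#' @param n_restarts random restarts, best objective kept (default 5).
#' @param seed integer seed.
#' @param lambda hinge-penalty weight (per cell) for barycentric
#'   violations; default 30 in robust mode, 2000 in enclosure mode. Low
#'   values place the vertices at the data's noise margin (robust
#'   archetype positions); high values force near-enclosure.
#' @param enclose if TRUE the fitted simplex is always inflated to the
#'   minimal homothety enclosing every cell — the volume the t-ratio
#'   compares against the data hull. Default FALSE (robust positions;
#'   snapped to enclosure only when that needs less than \code{snap_tol}
#'   relative inflation).
#' @param maxiter BFGS / ALS iteration cap.
#' @param snap_tol maximum relative inflation for snapping to full
#'   enclosure in robust mode (default 0.02).
#' @return a \code{simplex_fit}: \code{archetypes} (k x d), \code{weights}
#'   (cells x k, rows >= 0 summing to 1), \code{t_ratio} (when d <= 3),
#'   \code{objective}, \code{enclosed} (does the simplex enclose all
#'   cells), \code{max_violation} (worst barycentric shortfall),
#'   \code{seed}.
#' @export
fit_simplex <- function(scores, n_archetypes = ncol(scores) + 1L,
                        n_restarts = 5, seed = 1, lambda = NULL,
                        enclose = FALSE, maxiter = 120, snap_tol = 0.02) {
  if (is.null(lambda)) lambda <- if (enclose) 2000 else 30
  scores <- as.matrix(scores)
  n <- nrow(scores); d <- ncol(scores); k <- as.integer(n_archetypes)
  .assert(n >= k, "fewer cells (%d) than archetypes (%d)", n, k)
  .assert(k >= 2, "need at least 2 archetypes")
  ctr <- scale(scores, scale = FALSE)
  if (qr(ctr, tol = 1e-10)$rank < min(d, k - 1L)) {
    warning("degenerate simplex: data do not span the fitted dimensions; volume is ~0")
    ## rank-deficient data admit no meaningful simplex: report the most
    ## spread-out cells as vertices with uniform weights
    arch <- scores[.furthest_first(scores, k, 1L), , drop = FALSE]
    w <- matrix(1 / k, n, k)
    rownames(arch) <- paste0("A", seq_len(k))
    colnames(w) <- rownames(arch); rownames(w) <- rownames(scores)
    return(structure(list(archetypes = arch, weights = w,
                          t_ratio = NA_real_, p_value = NULL,
                          n_shuffles = 0L, objective = NA_real_,
                          enclosed = FALSE, max_violation = NA_real_,
                          n_dims = d, seed = seed),
                     class = "simplex_fit"))
  }
  set.seed(seed)
  if (k == d + 1L) {
    ## degenerate-but-exact case: k distinct points ARE the simplex
    uniq <- unique(scores)
    if (nrow(uniq) == k) {
      arch <- uniq
      bc <- .barycentric(scores, arch)
      w <- pmax(bc, 0); w <- w / rowSums(w)
      rownames(arch) <- paste0("A", seq_len(k))
      colnames(w) <- rownames(arch); rownames(w) <- rownames(scores)
      return(structure(list(
        archetypes = arch, weights = w,
        t_ratio = if (d <= 3) t_ratio(scores, arch) else NA_real_,
        p_value = NULL, n_shuffles = 0L, objective = 0,
        enclosed = TRUE, max_violation = 0, n_dims = d, seed = seed),
        class = "simplex_fit"))
    }
    X1 <- cbind(1, scores)
    best <- NULL
    for (r in seq_len(n_restarts)) {
      V0 <- scores[.furthest_first(scores, k, sample.int(n, 1)), ,
                   drop = FALSE]
      ## inflate the initial simplex about its centroid to enclose all
      bc0 <- tryCatch(.barycentric(scores, V0), error = function(e) NULL)
      if (is.null(bc0)) next
      f0 <- max(1, 1 - k * min(bc0)) * 1.001
      m0 <- colMeans(V0)
      V0 <- sweep(sweep(V0, 2, m0) * f0, 2, m0, "+")
      opt <- stats::optim(as.vector(V0), .mves_objective, .mves_gradient,
                          X1 = X1, d = d, lam_n = lambda / n,
                          method = "BFGS",
                          control = list(maxit = maxiter, reltol = 1e-12))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    .assert(!is.null(best), "simplex fitting failed on degenerate input")
    arch <- matrix(best$par, k, d)
    bc <- .barycentric(scores, arch)
    f_need <- max(1, 1 - k * min(bc))
    enclosed <- enclose || f_need <= 1 + snap_tol
    if (enclosed && f_need > 1) {
      m <- colMeans(arch)
      arch <- sweep(sweep(arch, 2, m) * f_need, 2, m, "+")
      bc <- bc / f_need + (1 - 1 / f_need) / k
    }
    w <- pmax(bc, 0); w <- w / rowSums(w)
    objective <- best$value
    max_violation <- max(0, -min(bc))
  } else {
    X <- t(scores)
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- .furthest_first(scores, k, sample.int(n, 1))
      fit <- .pcha(X, k, init, maxiter = maxiter)
      if (is.null(best) || fit$rss < best$rss) best <- fit
    }
    arch <- t(best$A)
    w <- t(best$S)
    objective <- best$rss
    enclosed <- FALSE
    max_violation <- NA_real_
  }
  rownames(arch) <- paste0("A", seq_len(k))
  colnames(w) <- rownames(arch)
  rownames(w) <- rownames(scores)
  tr <- if (d <= 3 && k >= d + 1L) t_ratio(scores, arch) else NA_real_
  structure(list(archetypes = arch, weights = w, t_ratio = tr,
                 p_value = NULL, n_shuffles = 0L, objective = objective,
                 enclosed = enclosed, max_violation = max_violation,
                 n_dims = d, seed = seed),
            class = "simplex_fit")
}

## barycentric coordinates of points x (n x d) w.r.t. simplex vertices
## v ((d+1) x d); rows sum to 1, negative outside.
.barycentric <- function(x, v) {
  d <- ncol(v)
  Tm <- t(v[-1, , drop = FALSE]) - v[1, ]      # d x d
  rel <- t(sweep(as.matrix(x), 2, v[1, ]))     # d x n
  lam <- solve(Tm, rel)                        # d x n (coords 2..d+1)
  t(rbind(1 - colSums(lam), lam))
}

#' @export
print.simplex_fit <- function(x, ...) {
  cat(sprintf("simplex_fit: %d archetypes in %d dims, %d cells\n",
              nrow(x$archetypes), x$n_dims, nrow(x$weights)))
  cat(sprintf("t-ratio: %s  enclosed: %s  objective: %.4g\n",
              ifelse(is.na(x$t_ratio), "NA", sprintf("%.4f", x$t_ratio)),
              x$enclosed, x$objective))
  if (!is.null(x$p_value))
    cat(sprintf("permutation p-value: %.4g (%d shuffles)\n",
                x$p_value, x$n_shuffles))
  invisible(x)
}

#' @export
summary.simplex_fit <- function(object, ...) {
  print(object)
  cat("archetype coordinates:\n")
  print(round(object$archetypes, 3))
  cat("mean archetype weight:",
      paste(sprintf("%.3f", colMeans(object$weights)), collapse = " "), "\n")
  invisible(object)
}

#' t-ratio of a fitted simplex
#'
#' Ratio of the simplex volume to the volume of the convex hull of the
#' data, both computed exactly in the d fitted dimensions. A value near 1
#' means the data fill the simplex; large values mean the simplex is a poor
#' (loose) description. Exact hulls are available for d <= 3, which covers
#' the study's 3D use.
#'
#' @param scores cells x d matrix.
#' @param archetypes k x d archetype coordinates (k = d + 1 for a simplex;
#'   for k > d + 1 the volume of the archetypes' hull is used).
#' @return the t-ratio (>= 1 for an enclosing simplex).
#' @export
t_ratio <- function(scores, archetypes) {
  scores <- as.matrix(scores); archetypes <- as.matrix(archetypes)
  d <- ncol(scores)
  .assert(ncol(archetypes) == d, "dimension mismatch")
  .assert(d <= 3, "t-ratio requires d <= 3 (exact hull volume)")
  vs <- if (nrow(archetypes) == d + 1L) .simplex_volume(archetypes)
        else convex_hull_volume(archetypes)
  vh <- convex_hull_volume(scores)
  if (vh == 0) .fail("degenerate data hull (zero volume)")
  vs / vh
}

#' Permutation test of the simplex fit (t-ratio test)
#'
#' Shuffles each PC column independently across cells, preserving each
#' coordinate's marginal distribution but destroying their correlation;
#' refits the simplex and recomputes the t-ratio on every shuffled dataset
#' with the identical fitting procedure. Fits run in enclosure mode (the
#' t-ratio compares the volume of the minimal simplex enclosing the data
#' against the data hull's volume, so it is at least 1; near 1 means the
#' data fill a simplex). Small t-ratios indicate tight simplex fits, so
#' the one-sided p-value is the add-one-smoothed fraction of shuffles with
#' a t-ratio at most the observed one.
#'
#' @param scores cells x d matrix of PC scores.
#' @param n_archetypes number of archetypes (default d + 1).
#' @param n_shuffles number of shuffled datasets (default 1000).
#' @param seed integer seed.
#' @param n_restarts,maxiter,lambda fitting controls applied identically to
#'   observed and shuffled data (fewer restarts keep the test affordable).
#' @return a \code{simplex_fit} with \code{p_value}, \code{n_shuffles} and
#'   the \code{null_t_ratios} vector filled in.
#' @export
t_ratio_test <- function(scores, n_archetypes = ncol(scores) + 1L,
                         n_shuffles = 1000, seed = 1, n_restarts = 2,
                         maxiter = 120, lambda = NULL) {
  if (n_shuffles < 19)
    warning("n_shuffles < 19: the attainable p-value floor is coarser than 0.05")
  scores <- as.matrix(scores)
  n <- nrow(scores)
  fit <- fit_simplex(scores, n_archetypes, n_restarts = n_restarts,
                     seed = derive_seed(seed, "observed"), enclose = TRUE,
                     maxiter = maxiter, lambda = lambda)
  null_t <- numeric(n_shuffles)
  for (b in seq_len(n_shuffles)) {
    set.seed(derive_seed(seed, paste0("shuffle", b)))
    perm <- apply(scores, 2, function(col) col[sample.int(n)])
    fb <- fit_simplex(perm, n_archetypes, n_restarts = n_restarts,
                      seed = derive_seed(seed, paste0("fit", b)),
                      enclose = TRUE, maxiter = maxiter, lambda = lambda)
    null_t[b] <- fb$t_ratio
  }
  fit$p_value <- (1 + sum(null_t <= fit$t_ratio)) / (1 + n_shuffles)
  fit$n_shuffles <- as.integer(n_shuffles)
  fit$null_t_ratios <- null_t
  fit
}

#' Euclidean distance of each cell to archetypes
#'
#' @param scores cells x d matrix.
#' @param archetypes k x d archetype coordinates.
#' @param which optional archetype index or name; default all.
#' @return cells x k distance matrix, or a vector if \code{which} is given.
#' @export
distance_to_archetype <- function(scores, archetypes, which = NULL) {
  scores <- as.matrix(scores); archetypes <- as.matrix(archetypes)
  d <- vapply(seq_len(nrow(archetypes)), function(j)
    sqrt(rowSums(sweep(scores, 2, archetypes[j, ])^2)),
    numeric(nrow(scores)))
  d <- matrix(d, nrow = nrow(scores))
  colnames(d) <- if (is.null(rownames(archetypes)))
    paste0("A", seq_len(nrow(archetypes))) else rownames(archetypes)
  rownames(d) <- rownames(scores)
  if (!is.null(which)) return(d[, which])
  d
}

#' Discretize cells by archetype proximity
#'
#' Each archetype's candidate set is the \code{frac_closest} fraction of
#' cells nearest to it; a cell claimed by several archetypes goes to the
#' nearest one. The \code{frac_generalist} fraction of cells nearest the
#' origin of the PC space is labeled "generalist", overriding archetype
#' labels (generalists sit at the simplex center, away from every
#' specialist vertex). Remaining cells are "unassigned".
#'
#' @param scores cells x d matrix of PC scores (centered, so the origin is
#'   the phenotypic average).
#' @param archetypes k x d archetype coordinates.
#' @param frac_closest fraction per archetype (default 0.25).
#' @param frac_generalist fraction labeled generalist (default 0.20).
#' @param origin coordinates of the generalist center (default zero).
#' @return character vector of labels per cell.
#' @export
discretize_archetypes <- function(scores, archetypes, frac_closest = 0.25,
                                  frac_generalist = 0.20,
                                  origin = rep(0, ncol(scores))) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- nrow(archetypes)
  d <- distance_to_archetype(scores, archetypes)
  m <- round(frac_closest * n)
  labels <- rep("unassigned", n)
  claimed <- matrix(FALSE, n, k)
  for (j in seq_len(k)) claimed[order(d[, j])[seq_len(m)], j] <- TRUE
  multi <- rowSums(claimed) > 0
  labels[multi] <- colnames(d)[apply(
    ifelse(claimed[multi, , drop = FALSE],
           d[multi, , drop = FALSE], Inf), 1, which.min)]
  g <- round(frac_generalist * n)
  d0 <- sqrt(rowSums(sweep(scores, 2, origin)^2))
  labels[order(d0)[seq_len(g)]] <- "generalist"
  stats::setNames(labels, rownames(scores))
}

#' Genes and pathway scores enriched near each archetype
#'
#' For every feature (gene, or mean-LTQ pathway score) and every archetype,
#' a two-sided Wilcoxon rank-sum test compares the \code{frac_closest}
#' member set against all other cells, with Benjamini-Hochberg q-values
#' across features within each archetype.
#'
#' @param ltq genes x cells matrix (or [ltq_matrix()]).
#' @param distances cells x k matrix from [distance_to_archetype()].
#' @param features gene ids to test (default all rows); an empty selection
#'   returns an empty table.
#' @param gene_sets optional named list of gene-id vectors; each set is
#'   tested as the per-cell mean LTQ over its genes.
#' @param frac_closest member-set fraction (default 0.25).
#' @return data.frame(feature, archetype, statistic, delta, p, q); delta is
#'   the member-minus-rest mean difference (positive = peaks at archetype).
#' @export
archetype_enrichment <- function(ltq, distances, features = NULL,
                                 gene_sets = NULL, frac_closest = 0.25) {
  if (inherits(ltq, "ltq_matrix")) ltq <- ltq$ltq
  if (is.null(features)) features <- rownames(ltq)
  feat <- ltq[features, , drop = FALSE]
  if (!is.null(gene_sets) && length(gene_sets)) {
    ps <- vapply(gene_sets, function(g)
      colMeans(ltq[intersect(g, rownames(ltq)), , drop = FALSE]),
      numeric(ncol(ltq)))
    feat <- rbind(feat, t(ps))
  }
  if (nrow(feat) == 0)
    return(data.frame(feature = character(), archetype = character(),
                      statistic = numeric(), delta = numeric(),
                      p = numeric(), q = numeric()))
  n <- ncol(feat)
  m <- round(frac_closest * n)
  out <- list()
  for (j in seq_len(ncol(distances))) {
    member <- seq_len(n) %in% order(distances[, j])[seq_len(m)]
    stat <- numeric(nrow(feat)); p <- numeric(nrow(feat))
    delta <- numeric(nrow(feat))
    for (i in seq_len(nrow(feat))) {
      x <- feat[i, member]; y <- feat[i, !member]
      wt <- stats::wilcox.test(x, y, exact = FALSE)
      stat[i] <- unname(wt$statistic); p[i] <- wt$p.value
      delta[i] <- mean(x) - mean(y)
    }
    out[[j]] <- data.frame(feature = rownames(feat),
                           archetype = colnames(distances)[j],
                           statistic = stat, delta = delta, p = p,
                           q = stats::p.adjust(p, "BH"))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Continuum-vs-cluster diagnostic on PC scores
#'
#' Estimates the cell density over the first two PCs, locates its local
#' maxima and their widths (full width at half maximum, from the area of
#' each peak's half-max region), and compares peak widths with the
#' measurement error (per-gene sampling errors propagated through the PCA
#' loadings and expressed as the FWHM a pure-noise cluster would show). If
#' every peak is no wider than \code{width_factor} times the
#' measurement-error FWHM — the factor absorbs the widening a finite KDE
#' bandwidth adds — the density is consistent with discrete clusters
#' blurred by noise ("cluster-like"); peaks much wider than the error
#' support a genuine phenotypic continuum ("continuum-like").
#'
#' @param scores cells x d matrix (first two columns used).
#' @param gene_error per-gene sampling errors (ignored if
#'   \code{error_sd} given).
#' @param loadings genes x PCs loading matrix matching \code{gene_error}.
#' @param error_sd per-coordinate measurement-error SD in score units;
#'   overrides propagation.
#' @param bandwidth KDE bandwidth (default: normal reference per axis).
#' @param grid_n KDE grid resolution (default 80).
#' @param min_height peaks below this fraction of the density maximum are
#'   ignored (default 0.05).
#' @param width_factor tolerance multiple on the error FWHM (default 1.5).
#' @return list: \code{peaks} (data.frame x, y, height, fwhm),
#'   \code{error_fwhm}, \code{verdict}
#'   ("cluster-like"/"continuum-like").
#' @export
continuum_diagnostic <- function(scores, gene_error = NULL, loadings = NULL,
                                 error_sd = NULL, bandwidth = NULL,
                                 grid_n = 80, min_height = 0.05,
                                 width_factor = 1.5) {
  s <- as.matrix(scores)[, 1:2, drop = FALSE]
  if (is.null(bandwidth))
    bandwidth <- c(MASS::bandwidth.nrd(s[, 1]),
                   MASS::bandwidth.nrd(s[, 2])) / 4
  ## bandwidth is the per-axis Gaussian kernel SD; kde2d's h is 4x the SD
  kd <- MASS::kde2d(s[, 1], s[, 2], h = 4 * bandwidth, n = grid_n)
  z <- kd$z
  nx <- nrow(z); ny <- ncol(z)
  ## local maxima on the grid (8-neighborhood), above the height floor
  is_peak <- matrix(FALSE, nx, ny)
  for (i in 2:(nx - 1)) for (j in 2:(ny - 1)) {
    nb <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (z[i, j] == max(nb) && sum(nb == z[i, j]) == 1 &&
        z[i, j] >= min_height * max(z))
      is_peak[i, j] <- TRUE
  }
  pk <- which(is_peak, arr.ind = TRUE)
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  peaks <- data.frame(x = numeric(), y = numeric(), height = numeric(),
                      fwhm = numeric())
  for (r in seq_len(nrow(pk))) {
    i <- pk[r, 1]; j <- pk[r, 2]; h <- z[i, j]
    ## flood fill the connected region above half max around the peak
    seen <- matrix(FALSE, nx, ny)
    stack <- list(c(i, j)); seen[i, j] <- TRUE; area_cells <- 0L
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      area_cells <- area_cells + 1L
      for (di in -1:1) for (dj in -1:1) {
        a <- cur[1] + di; b <- cur[2] + dj
        if (a >= 1 && a <= nx && b >= 1 && b <= ny && !seen[a, b] &&
            z[a, b] >= h / 2) {
          seen[a, b] <- TRUE
          stack[[length(stack) + 1L]] <- c(a, b)
        }
      }
    }
    area <- area_cells * dx * dy
    peaks <- rbind(peaks, data.frame(x = kd$x[i], y = kd$y[j], height = h,
                                     fwhm = 2 * sqrt(area / pi)))
  }
  if (is.null(error_sd)) {
    if (is.null(gene_error) || is.null(loadings))
      .fail("provide gene_error + loadings, or error_sd")
    pv <- colSums((loadings[, 1:2, drop = FALSE]^2) * gene_error^2)
    error_sd <- sqrt(mean(pv))
  }
  error_fwhm <- 2 * sqrt(2 * log(2)) * error_sd  # FWHM of a noise blob
  verdict <- if (nrow(peaks) && all(peaks$fwhm <= width_factor * error_fwhm))
    "cluster-like" else "continuum-like"
  list(peaks = peaks, error_fwhm = error_fwhm, verdict = verdict,
       bandwidth = bandwidth)
}
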