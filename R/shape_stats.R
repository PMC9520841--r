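## Multivariate statistics on tangent-space shape coordinates:
## Procrustes ANOVA (Goodall-style isotropic model), canonical variate
## analysis, permutation tests on group distances, two-group discriminant
## function analysis and leave-one-out cross-validation.

.asFactor <- function(x) if (is.factor(x)) droplevels(x) else factor(x)

#' Procrustes ANOVA for a sex-by-species factorial design
#'
#' Goodall-style isotropic shape ANOVA: sequential (Type I) sums of squares
#' are computed coordinate-wise from nested least-squares fits, in the
#' order sex, species, sex x species, and summed over all 2p tangent
#' coordinates. Degrees of freedom are the univariate effect df multiplied
#' by the shape-space dimension 2p - 4; the residual df is
#' (n - cells) x (2p - 4). With the default \code{error_stratum =
#' "interaction"} the main effects are tested against the interaction mean
#' square and the interaction against the residual — the convention behind
#' published flea-head shape ANOVA tables (e.g. MS 0.00558 over MS 0.000145
#' gives F = 38.49). \code{error_stratum = "residual"} tests every effect
#' against the residual mean square (the plain Goodall convention).
#'
#' @param tangent n x 2p tangent coordinate matrix (see [tangentProject()]).
#' @param sex factor (2 levels).
#' @param species factor (2 levels).
#' @param order character vector giving the sequential order of the two
#'   main effects (default \code{c("sex", "species")}); the interaction is
#'   always last.
#' @param error_stratum "interaction" (default) or "residual"; the error
#'   mean square for the two main effects.
#' @return data.frame with rows sex, species, sex:species, residual and
#'   columns effect, SS, MS, df, F, p.
#' @examples
#' ## a 165-specimen, 13-landmark, 2x2 dataset has df (22, 22, 22, 3542)
#' @export
procrustesAnova <- function(tangent, sex, species,
                            order = c("sex", "species"),
                            error_stratum = c("interaction", "residual")) {
  error_stratum <- match.arg(error_stratum)
  tangent <- as.matrix(tangent)
  sex <- .asFactor(sex); species <- .asFactor(species)
  n <- nrow(tangent)
  if (length(sex) != n || length(species) != n)
    stop("factor lengths must match the number of specimens")
  if (nlevels(sex) != 2L || nlevels(species) != 2L)
    stop("sex and species must each have exactly 2 levels")
  cells <- interaction(sex, species, drop = FALSE)
  if (any(table(cells) == 0L)) stop("design error: empty sex x species cell")
  if (n <= nlevels(cells)) stop("need more specimens than cells")
  order <- match.arg(order, c("sex", "species"), several.ok = TRUE)
  if (length(order) != 2L || anyDuplicated(order))
    stop("order must be a permutation of c('sex','species')")
  fac <- list(sex = sex, species = species)
  f1 <- fac[[order[1]]]; f2 <- fac[[order[2]]]

  p2 <- ncol(tangent)
  if (p2 %% 2L != 0L) stop("tangent matrix must have 2p columns")
  shape_dim <- p2 - 4L                     # 2p - 4 shape dimensions
  if (shape_dim < 1L) stop("need at least 3 landmarks (2p - 4 >= 1)")

  rss <- function(mm) {
    Q <- qr(mm)
    sum(qr.resid(Q, tangent)^2)
  }
  rss0 <- rss(matrix(1, n, 1))
  rss1 <- rss(stats::model.matrix(~f1))
  rss2 <- rss(stats::model.matrix(~f1 + f2))
  rss3 <- rss(stats::model.matrix(~f1 * f2))
  ss <- c(rss0 - rss1, rss1 - rss2, rss2 - rss3, rss3)
  df <- c(shape_dim, shape_dim, shape_dim,
          (n - nlevels(cells)) * shape_dim)
  ms <- ss / df
  den <- if (error_stratum == "interaction") c(3L, 3L, 4L) else c(4L, 4L, 4L)
  Fv <- c(ms[1:3] / ms[den], NA_real_)
  pv <- c(pf(Fv[1:3], df[1:3], df[den], lower.tail = FALSE), NA_real_)
  # degenerate data: total SS indistinguishable from roundoff
  if (rss0 <= sqrt(.Machine$double.eps) * max(1, sum(tangent^2)) ||
      any(ms[den] == 0)) {
    ss[] <- pmax(ss, 0)
    Fv[1:3] <- NaN; pv[1:3] <- NaN
    warning("zero shape variance: F undefined")
  }
  data.frame(
    effect = c(paste("flea", order[1]), paste("flea", order[2]),
               "flea sex x species", "residual"),
    SS = ss, MS = ms, df = df, F = Fv, p = pv,
    stringsAsFactors = FALSE)
}

# pooled within-group covariance (divisor n - g) of Y given group factor
.pooledWithin <- function(Y, g) {
  n <- nrow(Y)
  W <- matrix(0, ncol(Y), ncol(Y))
  for (lv in levels(g)) {
    Yi <- Y[g == lv, , drop = FALSE]
    Yc <- sweep(Yi, 2, colMeans(Yi))
    W <- W + crossprod(Yc)
  }
  W / (n - nlevels(g))
}

# project Y onto the principal subspace of the pooled within-group
# covariance (relative eigenvalue > rel_tol); returns reduced data and basis
.withinSubspace <- function(Y, g, rel_tol = 1e-9) {
  W <- .pooledWithin(Y, g)
  e <- eigen(W, symmetric = TRUE)
  keep <- e$values > max(e$values) * rel_tol
  if (!any(keep)) stop("zero within-group variance: rank error")
  basis <- e$vectors[, keep, drop = FALSE]
  list(Yr = Y %*% basis, basis = basis, values = e$values[keep])
}

# Mahalanobis distances between group means in (already reduced) space,
# using the pooled within-group covariance with divisor n - g
.mahalanobisBetweenMeans <- function(Yr, g) {
  W <- .pooledWithin(Yr, g)
  Winv <- solve(W)
  lv <- levels(g)
  means <- t(vapply(lv, function(l) colMeans(Yr[g == l, , drop = FALSE]),
                    numeric(ncol(Yr))))
  D <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
    d <- means[i, ] - means[j, ]
    D[i, j] <- D[j, i] <- sqrt(drop(t(d) %*% Winv %*% d))
  }
  D
}

# Euclidean distances between group means (Procrustes distance between
# group mean shapes, to tangent-space approximation)
.procrustesBetweenMeans <- function(Y, g) {
  lv <- levels(g)
  means <- t(vapply(lv, function(l) colMeans(Y[g == l, , drop = FALSE]),
                    numeric(ncol(Y))))
  D <- as.matrix(dist(means))
  dimnames(D) <- list(lv, lv)
  D
}

#' Canonical variate analysis
#'
#' Ordination maximizing between-group relative to within-group variation.
#' Tangent coordinates are first projected onto the principal subspace of
#' the pooled within-group covariance (relative eigenvalue > 1e-9) to
#' handle the rank deficiency of Procrustes data; the canonical axes then
#' solve the between/within generalized eigenproblem in that subspace and
#' are scaled so the pooled within-group variance of each score is 1.
#' Pairwise Mahalanobis distances between group means use the pooled
#' within-group covariance (divisor n - g). When \code{n_perm > 0},
#' permutation p-values for both Mahalanobis and Procrustes distances are
#' computed via [permutationGroupTest()].
#'
#' @param tangent n x 2p matrix of tangent coordinates.
#' @param groups factor (g >= 2 levels, each with >= 2 specimens).
#' @param n_perm permutation rounds for the pairwise tests (default 10000;
#'   0 skips them).
#' @param seed integer RNG seed recorded in the result.
#' @return A \linkS4class{CvaFit}.
#' @export
cva <- function(tangent, groups, n_perm = 10000L, seed = 1L) {
  Y <- as.matrix(tangent)
  g <- .asFactor(groups)
  if (length(g) != nrow(Y)) stop("groups length must match specimens")
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs >= 2 specimens")
  red <- .withinSubspace(Y, g)
  Yr <- red$Yr
  W <- .pooledWithin(Yr, g)
  lv <- levels(g)
  ng <- as.numeric(table(g))
  means <- t(vapply(lv, function(l) colMeans(Yr[g == l, , drop = FALSE]),
                    numeric(ncol(Yr))))
  grand <- colMeans(Yr)
  Mc <- sweep(means, 2, grand)
  B <- crossprod(Mc * sqrt(ng)) / (nlevels(g) - 1)
  # whiten by W: solve W^{-1/2} B W^{-1/2} symmetric eigenproblem
  eW <- eigen(W, symmetric = TRUE)
  Wmh <- eW$vectors %*% diag(1 / sqrt(eW$values), length(eW$values)) %*%
    t(eW$vectors)
  eB <- eigen(Wmh %*% B %*% Wmh, symmetric = TRUE)
  k <- min(nlevels(g) - 1L, ncol(Yr))
  eigenvalues <- pmax(eB$values[seq_len(k)], 0)
  axes_r <- Wmh %*% eB$vectors[, seq_len(k), drop = FALSE]  # a' W a = I
  scores <- sweep(Yr, 2, grand) %*% axes_r
  gm <- sweep(means, 2, grand) %*% axes_r
  pct <- if (sum(eigenvalues) > 0) 100 * eigenvalues / sum(eigenvalues)
         else rep(0, k)
  maha <- .mahalanobisBetweenMeans(Yr, g)
  proc <- .procrustesBetweenMeans(Y, g)
  pv <- list(
    mahalanobis = matrix(NA_real_, nlevels(g), nlevels(g),
                         dimnames = dimnames(maha)),
    procrustes = matrix(NA_real_, nlevels(g), nlevels(g),
                        dimnames = dimnames(proc)))
  if (n_perm > 0) {
    pv$mahalanobis <- permutationGroupTest(Y, g, statistic = "mahalanobis",
                                           n_perm = n_perm, seed = seed)
    pv$procrustes <- permutationGroupTest(Y, g, statistic = "procrustes",
                                          n_perm = n_perm, seed = seed)
  }
  colnames(scores) <- colnames(gm) <- paste0("CV", seq_len(k))
  new("CvaFit",
      axes = red$basis %*% axes_r,
      eigenvalues = eigenvalues, percentVar = pct,
      scores = scores, groupMeans = gm,
      mahalanobis = maha, procrustes = proc,
      pValues = pv, groups = g,
      nPerm = as.integer(n_perm), seed = as.integer(seed))
}

#' Permutation tests for pairwise group distances
#'
#' For every pair of groups, specimens of the two groups are pooled and
#' their labels permuted \code{n_perm} times; the observed between-mean
#' distance (Mahalanobis, recomputed in the permuted groups' pooled
#' within-covariance subspace, or Procrustes, i.e. Euclidean in tangent
#' space) is compared against the permutation distribution. The p-value is
#' (b + 1) / (n_perm + 1) where b counts permuted distances >= observed
#' (ties count as extreme). Deterministic given \code{seed}.
#'
#' @param tangent n x 2p tangent coordinates.
#' @param groups factor (>= 2 levels).
#' @param statistic "mahalanobis" or "procrustes".
#' @param n_perm permutation rounds (default 10000).
#' @param seed integer RNG seed.
#' @return symmetric g x g matrix of p-values (NA diagonal).
#' @export
permutationGroupTest <- function(tangent, groups,
                                 statistic = c("mahalanobis", "procrustes"),
                                 n_perm = 10000L, seed = 1L) {
  Y <- as.matrix(tangent)
  g <- .asFactor(groups)
  statistic <- match.arg(statistic)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  lv <- levels(g)
  P <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  pair_stat <- function(Yp, lab) {
    if (statistic == "procrustes") {
      m1 <- colMeans(Yp[lab == 1L, , drop = FALSE])
      m2 <- colMeans(Yp[lab == 2L, , drop = FALSE])
      sqrt(sum((m1 - m2)^2))
    } else {
      f <- factor(lab)
      red <- .withinSubspace(Yp, f)
      .mahalanobisBetweenMeans(red$Yr, f)[1, 2]
    }
  }
  set.seed(seed)
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
    sel <- g %in% lv[c(i, j)]
    Yp <- Y[sel, , drop = FALSE]
    lab <- ifelse(g[sel] == lv[i], 1L, 2L)
    obs <- pair_stat(Yp, lab)
    b <- 0L
    for (r in seq_len(n_perm)) {
      perm <- sample(lab)
      if (pair_stat(Yp, perm) >= obs) b <- b + 1L
    }
    P[i, j] <- P[j, i] <- (b + 1) / (n_perm + 1)
  }
  P
}

# fit the two-group discriminant pipeline on (Y, g): within-subspace
# reduction, axis = W^{-1} (mu1 - mu2), midpoint cutoff
.dfaFit <- function(Y, g) {
  red <- .withinSubspace(Y, g)
  Yr <- red$Yr
  W <- .pooledWithin(Yr, g)
  lv <- levels(g)
  m1 <- colMeans(Yr[g == lv[1], , drop = FALSE])
  m2 <- colMeans(Yr[g == lv[2], , drop = FALSE])
  a_r <- solve(W, m1 - m2)
  s1 <- drop(m1 %*% a_r); s2 <- drop(m2 %*% a_r)
  list(axis_r = a_r, basis = red$basis, cutoff = (s1 + s2) / 2,
       sign1 = sign(s1 - s2))   # group 1 lies on this side of the cutoff
}

.dfaClassify <- function(fit, Ynew) {
  s <- drop(as.matrix(Ynew) %*% fit$basis %*% fit$axis_r)
  ifelse(fit$sign1 * (s - fit$cutoff) >= 0, 1L, 2L)
}

#' Two-group discriminant function analysis
#'
#' Classical two-group DFA on tangent coordinates: after reduction onto the
#' pooled within-group covariance subspace, the discriminant axis is
#' W^-1 (mu1 - mu2); specimens are classified by their score against the
#' midpoint of the two group mean scores. Reports the resubstitution
#' contingency table and, when \code{n_perm > 0}, a permutation p-value for
#' the Mahalanobis distance between group means. Use [looCrossValidate()]
#' for the leave-one-out table.
#'
#' @param tangent n x 2p tangent coordinates.
#' @param groups factor with exactly 2 levels, each with >= 2 specimens.
#' @param n_perm permutation rounds (default 10000; 0 skips the test).
#' @param seed integer RNG seed.
#' @param loo logical; also run leave-one-out cross-validation.
#' @return A \linkS4class{DfaFit}.
#' @export
dfaTwoGroup <- function(tangent, groups, n_perm = 10000L, seed = 1L,
                        loo = TRUE) {
  Y <- as.matrix(tangent)
  g <- .asFactor(groups)
  if (nlevels(g) != 2L) stop("DFA requires exactly 2 groups")
  if (any(table(g) < 2L)) stop("both groups need >= 2 specimens")
  fit <- .dfaFit(Y, g)
  scores <- drop(Y %*% fit$basis %*% fit$axis_r)
  assigned <- levels(g)[.dfaClassify(fit, Y)]
  resub <- table(true = g, assigned = factor(assigned, levels = levels(g)))
  resub <- unclass(as.matrix(resub))
  permP <- NA_real_
  if (n_perm > 0)
    permP <- permutationGroupTest(Y, g, "mahalanobis", n_perm, seed)[1, 2]
  out <- new("DfaFit", axis = drop(fit$basis %*% fit$axis_r),
             scores = scores, cutoff = fit$cutoff,
             resubstitution = resub,
             loo = matrix(0L, 2, 2, dimnames = dimnames(resub)),
             looRates = c(NA_real_, NA_real_),
             permutationP = permP, groups = g,
             nPerm = as.integer(n_perm), seed = as.integer(seed))
  if (loo) {
    cvres <- looCrossValidate(Y, g)
    out@loo <- cvres$table
    out@looRates <- cvres$rates
  }
  out
}

#' Leave-one-out cross-validation of the two-group discriminant pipeline
#'
#' For every specimen, the full pipeline (within-subspace reduction, axis,
#' midpoint cutoff) is refit on the remaining n - 1 specimens and the
#' held-out specimen is classified. Specimens whose refit fails (rank
#' collapse) are counted as unclassifiable and excluded from the table.
#'
#' @param tangent n x 2p tangent coordinates.
#' @param groups factor with two levels, each with >= 3 specimens.
#' @return list with \code{table} (2 x 2, rows = true group),
#'   \code{rates} (per-group misclassification rates) and
#'   \code{unclassifiable} (count).
#' @export
looCrossValidate <- function(tangent, groups) {
  Y <- as.matrix(tangent)
  g <- .asFactor(groups)
  if (nlevels(g) != 2L) stop("LOO cross-validation requires 2 groups")
  if (any(table(g) < 3L)) stop("both groups need >= 3 specimens")
  n <- nrow(Y)
  lv <- levels(g)
  tab <- matrix(0L, 2, 2, dimnames = list(true = lv, assigned = lv))
  unclassifiable <- 0L
  for (i in seq_len(n)) {
    fit <- tryCatch(.dfaFit(Y[-i, , drop = FALSE], g[-i]),
                    error = function(e) NULL)
    if (is.null(fit)) { unclassifiable <- unclassifiable + 1L; next }
    cls <- .dfaClassify(fit, Y[i, , drop = FALSE])
    tab[as.integer(g[i]), cls] <- tab[as.integer(g[i]), cls] + 1L
  }
  rates <- 1 - diag(tab) / pmax(rowSums(tab), 1L)
  names(rates) <- lv
  list(table = tab, rates = rates, unclassifiable = unclassifiable)
}

#' Improvement of morphometric over observer classification
#'
#' Compares per-class misclassification rates between an observer
#' (traditional morphological key) contingency table and a morphometric
#' (e.g. LOO) table sharing the same class labels. Rates are rounded to
#' whole percent (half away from zero) and the fold improvement is the
#' ratio of the rounded rates, to one decimal — the convention used when
#' reporting e.g. "from 31 to 6% (5.2-fold improvement)".
#'
#' @param observer_table square contingency matrix, rows = true class.
#' @param loo_table square contingency matrix with the same labels.
#' @return data.frame with class, rate_before (%), rate_after (%), fold;
#'   fold is Inf (with a warning) when the after-rate is 0.
#' @examples
#' before <- rbind(c(35, 16), c(4, 3))   # 16/51 = 31% misclassified
#' after  <- rbind(c(44,  3), c(1, 6))   # 3/47 = 6%
#' @export
classificationImprovement <- function(observer_table, loo_table) {
  ob <- as.matrix(observer_table); lo <- as.matrix(loo_table)
  if (!identical(dim(ob), dim(lo)) || nrow(ob) != ncol(ob))
    stop("tables must be square with matching class labels")
  if (!is.null(rownames(ob)) && !is.null(rownames(lo)) &&
      !identical(rownames(ob), rownames(lo)))
    stop("tables must share class labels")
  cls <- rownames(ob)
  if (is.null(cls)) cls <- as.character(seq_len(nrow(ob)))
  rate <- function(m) {
    wrong <- rowSums(m) - diag(m)
    .roundHalfAway(100 * wrong / rowSums(m), 0)
  }
  before <- rate(ob); after <- rate(lo)
  fold <- round(before / after, 1)
  if (any(is.infinite(fold)))
    warning("zero post-classification error: fold improvement infinite")
  data.frame(class = cls, rate_before = before, rate_after = after,
             fold = fold, row.names = NULL)
}

# round half away from zero (base round() is half-even)
.roundHalfAway <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
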