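#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of average ranks (ties averaged); the
#' two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' with `p = 0` at `|rho| = 1`.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return List with elements `rho` and `p`.
#' @export
spearmanRho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stopf("x and y lengths differ")
  if (n < 3L) stopf("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("Spearman correlation undefined for a constant vector")
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) return(list(rho = sign(rho), p = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Select the optimal gray-level bin width for one feature
#'
#' Picks the bin width whose feature values correlate most strongly (largest
#' `|rho|`) with the onset ages. A constant feature vector scores
#' `|rho| = 0`; exact ties resolve to the smallest width.
#'
#' @param values named list (or matrix rows) keyed by bin width, each a
#'   numeric vector of per-subject feature values.
#' @param ages onset ages aligned with the value vectors.
#' @return List with `width`, `rho`.
#' @export
selectBinWidth <- function(values, ages) {
  ws <- sort(as.integer(names(values)))
  if (!length(ws)) stopf("no bin widths supplied")
  rhos <- vapply(as.character(ws), function(w) {
    v <- values[[w]]
    if (length(v) != length(ages))
      stopf("width %s has %d values for %d ages", w, length(v), length(ages))
    if (sd(v) == 0 || sd(ages) == 0) return(0)
    spearmanRho(v, ages)$rho
  }, numeric(1))
  best <- which.max(abs(rhos))      # first max = smallest width on ties
  list(width = ws[best], rho = rhos[[best]])
}

#' Cohort-level optimal bin width per feature
#'
#' Selects one bin width per feature, shared by every region: for each
#' (feature, width) the absolute Spearman correlation of the feature values
#' with the onset ages is computed within each region and averaged over
#' regions; the width maximizing this average wins, ties resolving to the
#' smallest width. Sharing the selection across regions keeps the
#' adaptivity of the maximal-correlation rule while diluting, by the number
#' of regions, the circularity of selecting on the same ages that later
#' screen the components (see the methods vignette).
#'
#' @param features long feature data.frame over all regions and widths.
#' @param ages named numeric vector of onset ages (names = subject ids).
#' @return data.frame with columns `feature` (`family_Name`), `binWidth`,
#'   `meanAbsRho`.
#' @export
selectCohortWidths <- function(features, ages) {
  subjects <- names(ages)
  sub <- features[features$subject_id %in% subjects, , drop = FALSE]
  rAges <- rank(unname(ages))
  key <- paste(sub$family, sub$feature_name, sep = "_")
  feats <- unique(key)
  # one pass of index bookkeeping instead of repeated data.frame scans
  grp <- split(seq_len(nrow(sub)),
               list(key, sub$bin_width, sub$region), drop = TRUE)
  sidx <- match(sub$subject_id, subjects)
  out <- data.frame(feature = feats, binWidth = NA_integer_,
                    meanAbsRho = NA_real_, stringsAsFactors = FALSE)
  ws <- sort(unique(sub$bin_width))
  regs <- sort(unique(sub$region))
  for (fi in seq_along(feats)) {
    agg <- vapply(ws, function(w) {
      mean(vapply(regs, function(r) {
        ix <- grp[[paste(feats[fi], w, r, sep = ".")]]
        if (is.null(ix))
          stopf("incomplete feature table: feature %s, width %d, region %s",
                feats[fi], w, r)
        v <- numeric(length(subjects))
        v[sidx[ix]] <- sub$value[ix]
        if (length(ix) != length(subjects) || anyNA(v))
          stopf("incomplete feature table: feature %s, width %d, region %s",
                feats[fi], w, r)
        if (sd(v) == 0) 0 else abs(cor(rank(v), rAges))
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(agg)            # first max = smallest width on ties
    out$binWidth[fi] <- ws[best]
    out$meanAbsRho[fi] <- agg[best]
  }
  out
}

#' Per-region PCA of the bin-width-selected feature matrix
#'
#' For one region: selects the optimal bin width per feature with
#' [selectBinWidth()], z-scores each selected feature across subjects
#' (population normalization), drops zero-variance features, and
#' eigendecomposes the resulting correlation structure. The number of
#' retained components `nInd` is the smallest k whose cumulative explained
#' variance reaches `varianceThreshold`. Component signs are fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param table long feature data.frame (as produced by [extractFeatures()]
#'   stacked over subjects) restricted to the AD group or not -- the caller
#'   decides; must contain columns `subject_id`, `region`, `feature_id`,
#'   `feature_name`, `family`, `bin_width`, `value`.
#' @param region atlas label to analyze.
#' @param ages named numeric vector of onset ages, names = subject ids.
#' @param varianceThreshold cumulative explained-variance target
#'   (default 0.90).
#' @param widthMap optional fixed width per feature (named integer vector,
#'   names `family_Name`, e.g. from [selectCohortWidths()]); when given,
#'   the per-region width selection is skipped and `selectedWidths$rho`
#'   reports the region's own Spearman rho at the fixed width.
#' @return A [RegionPca-class].
#' @export
regionPca <- function(table, region, ages, varianceThreshold = 0.90,
                      widthMap = NULL) {
  sub <- table[table$region == region, , drop = FALSE]
  if (!nrow(sub)) stopf("region %s absent from feature table", region)
  subjects <- names(ages)
  if (length(subjects) < 3L) stopf("need at least 3 subjects for PCA")
  sub <- sub[sub$subject_id %in% subjects, , drop = FALSE]
  key <- paste(sub$family, sub$feature_name, sep = "_")
  feats <- unique(key)
  sel <- data.frame(feature = feats,
                    binWidth = NA_integer_, rho = NA_real_,
                    stringsAsFactors = FALSE)
  x <- matrix(NA_real_, nrow = length(subjects), ncol = length(feats),
              dimnames = list(subjects, feats))
  grp <- split(seq_len(nrow(sub)), list(key, sub$bin_width), drop = TRUE)
  sidx <- match(sub$subject_id, subjects)
  allWs <- sort(unique(sub$bin_width))
  for (fi in seq_along(feats)) {
    ws <- allWs[vapply(allWs, function(w)
      !is.null(grp[[paste(feats[fi], w, sep = ".")]]), logical(1))]
    vals <- lapply(ws, function(w) {
      ix <- grp[[paste(feats[fi], w, sep = ".")]]
      v <- rep(NA_real_, length(subjects))
      v[sidx[ix]] <- sub$value[ix]
      if (anyNA(v))
        stopf("incomplete feature table: region %s, feature %s, width %d",
              region, feats[fi], w)
      v
    })
    names(vals) <- ws
    if (is.null(widthMap)) {
      pick <- selectBinWidth(vals, unname(ages))
    } else {
      w <- widthMap[[feats[fi]]]
      if (is.null(w) || !as.character(w) %in% names(vals))
        stopf("widthMap has no usable width for feature %s", feats[fi])
      v <- vals[[as.character(w)]]
      rho <- if (sd(v) == 0 || sd(ages) == 0) 0
             else spearmanRho(v, unname(ages))$rho
      pick <- list(width = as.integer(w), rho = rho)
    }
    sel$binWidth[fi] <- pick$width
    sel$rho[fi] <- pick$rho
    x[, fi] <- vals[[as.character(pick$width)]]
  }
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(sweep(x, 2, mu)^2))
  dropped <- colnames(x)[sigma < 1e-12]
  keep <- sigma >= 1e-12
  if (length(dropped))
    petLog("pca", "region %s: dropped %d zero-variance features", region,
           length(dropped), verbose = FALSE)
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sigma[keep], "/")
  cmat <- crossprod(z) / nrow(z)      # correlation matrix, population scaling
  eg <- eigen(cmat, symmetric = TRUE)
  evr <- pmax(eg$values, 0) / sum(pmax(eg$values, 0))
  load <- eg$vectors
  # sign convention: dominant loading positive
  for (k in seq_len(ncol(load))) {
    jmax <- which.max(abs(load[, k]))
    if (load[jmax, k] < 0) load[, k] <- -load[, k]
  }
  rownames(load) <- colnames(z)
  scores <- z %*% load
  nInd <- which(cumsum(evr) >= varianceThreshold - 1e-12)[1]
  new("RegionPca", region = as.integer(region), selectedWidths = sel,
      loadings = load, explainedVar = evr, nInd = as.integer(nInd),
      scores = scores, dropped = dropped,
      center = mu[keep], scale = sigma[keep])
}

#' Screen retained components against onset age
#'
#' Spearman-correlates each retained component's scores with onset age. A
#' component is significant when `|rho| > rhoThreshold` and
#' `p < alpha / nInd` -- the Bonferroni correction over the region's
#' retained components. For each component, the features loading within 90%
#' of its largest absolute coefficient are reported as top features.
#'
#' @param pca a [RegionPca-class].
#' @param ages onset ages aligned with the score rows.
#' @param rhoThreshold correlation threshold (default 0.5).
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame, one row per retained component: `region`,
#'   `component` (0-based, leading component is 0), `explainedVar`, `rho`,
#'   `p`, `pThreshold`, `significant`, `topFeatures` (comma-separated).
#' @export
screenComponents <- function(pca, ages, rhoThreshold = 0.5, alpha = 0.05) {
  nInd <- pca@nInd
  thr <- alpha / nInd
  res <- lapply(seq_len(nInd), function(k) {
    sc <- pca@scores[, k]
    if (sd(sc) == 0) {
      rho <- 0; p <- 1
    } else {
      sp <- spearmanRho(sc, ages)
      rho <- sp$rho; p <- sp$p
    }
    cj <- abs(pca@loadings[, k])
    top <- rownames(pca@loadings)[cj > 0.9 * max(cj)]
    data.frame(region = pca@region, component = k - 1L,
               explainedVar = pca@explainedVar[k], rho = rho, p = p,
               pThreshold = thr,
               significant = abs(rho) > rhoThreshold & p < thr,
               topFeatures = paste(top, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pooled-variance two-sample Student's t-test
#'
#' Two-sided test on the difference of means with the pooled variance
#' estimate and `n1 + n2 - 2` degrees of freedom. When the pooled variance
#' is zero the test degenerates: equal means give `t = 0, p = 1`, separated
#' means give an infinite statistic with `p = 0`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch if `TRUE`, use the Welch unequal-variance form instead.
#' @return List with `t`, `df`, `p`.
#' @export
pooledTTest <- function(a, b, welch = FALSE) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stopf("both groups need at least 2 members")
  if (welch) {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    return(list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value))
  }
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0))
  }
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df = df))
}

#' Threshold-age scan of a component's scores
#'
#' For each candidate threshold age A on an integer grid, splits the AD
#' subjects into onset < A and onset >= A and, when both groups have at
#' least 2 members, tests the component scores with [pooledTTest()]. The
#' significant range is the set of A with `p < alpha / nInd`.
#'
#' @param scores component scores of the AD subjects.
#' @param ages their onset ages.
#' @param nInd the region's Bonferroni divisor (retained components).
#' @param ageRange integer scan bounds, default 55 to 75.
#' @param alpha family-wise level (default 0.05).
#' @param welch use Welch's test instead of pooled Student's t.
#' @return data.frame with columns `A`, `n_early`, `n_late`, `p`
#'   (NA where a group is smaller than 2), `significant`.
#' @export
thresholdAgeScan <- function(scores, ages, nInd, ageRange = c(55L, 75L),
                             alpha = 0.05, welch = FALSE) {
  grid <- seq(as.integer(ageRange[1]), as.integer(ageRange[2]))
  thr <- alpha / nInd
  rows <- lapply(grid, function(A) {
    e <- scores[ages < A]; l <- scores[ages >= A]
    p <- if (length(e) >= 2L && length(l) >= 2L)
      pooledTTest(e, l, welch = welch)$p else NA_real_
    data.frame(A = A, n_early = length(e), n_late = length(l), p = p,
               significant = !is.na(p) & p < thr)
  })
  do.call(rbind, rows)
}
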