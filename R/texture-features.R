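# Canonical registry of the 93-feature battery. Feature ids follow the fixed
# battery order: GLDM 1-14, GLSZM 15-30, GLCM 31-54, NGTDM 55-59,
# GLRLM 60-75, first order 76-93. Gray levels enter all intensity-weighted
# formulas as 1-based values (level + 1).

FEATURE_NAMES <- list(
  GLDM = c("DependenceEntropy", "DependenceNonUniformity",
           "DependenceNonUniformityNormalized", "DependenceVariance",
           "GrayLevelNonUniformity", "GrayLevelVariance",
           "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
           "LargeDependenceHighGrayLevelEmphasis",
           "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
           "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
           "SmallDependenceLowGrayLevelEmphasis"),
  GLSZM = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
            "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
            "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
            "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
            "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
            "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy", "ZonePercentage",
            "ZoneVariance"),
  GLCM = c("Autocorrelation", "ClusterProminence", "ClusterShade",
           "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
           "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
           "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
           "JointEnergy", "JointEntropy", "MCC", "MaximumProbability",
           "SumAverage", "SumEntropy", "SumSquares"),
  NGTDM = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength"),
  GLRLM = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "GrayLevelVariance", "HighGrayLevelRunEmphasis",
            "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
            "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
            "RunEntropy", "RunLengthNonUniformity",
            "RunLengthNonUniformityNormalized", "RunPercentage",
            "RunVariance", "ShortRunEmphasis",
            "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis"),
  FIRSTORDER = c("Percentile10", "Percentile90", "Energy", "Entropy",
                 "InterquartileRange", "Kurtosis", "MeanAbsoluteDeviation",
                 "Mean", "Median", "RobustMeanAbsoluteDeviation",
                 "RootMeanSquared", "Skewness", "TotalEnergy", "Uniformity",
                 "Variance", "Maximum", "Minimum", "Range")
)

#' The 93-feature registry
#'
#' One row per feature of the battery: integer id (1..93), matrix family,
#' feature name, and the canonical column id `<family>_<Name>` used in all
#' long-format outputs.
#'
#' @param duplicateEntropy if `TRUE`, feature 80 is reported as a verbatim
#'   duplicate of the first-order Entropy instead of the interquartile range
#'   (see the methods vignette on this choice).
#' @return A data.frame with columns `id`, `family`, `name`, `column`.
#' @export
featureRegistry <- function(duplicateEntropy = FALSE) {
  fam <- rep(names(FEATURE_NAMES), lengths(FEATURE_NAMES))
  nm <- unlist(FEATURE_NAMES, use.names = FALSE)
  if (duplicateEntropy) nm[80] <- "Entropy2"
  data.frame(id = seq_along(nm), family = fam, name = nm,
             column = paste(tolower(fam), nm, sep = "_"),
             stringsAsFactors = FALSE)
}

#' Features of a gray-level co-occurrence matrix
#'
#' The 24 GLCM features of the battery, computed on the matrix normalized to
#' sum 1. All sums run over the nonzero entries of the (typically very
#' sparse) matrix; the marginal-product entropy HXY2 uses the identity
#' `HXY2 = HX + HY` that holds for probability marginals. Degenerate cases
#' follow the package's documented conventions: `0 * log 0 = 0`; Correlation
#' and Imc1 are 0 when their denominator vanishes; MCC is 1 when fewer than
#' two gray levels occur; a VOI with no neighbor pairs yields all-zero
#' features.
#'
#' @param m a GLCM [TextureMatrix-class] from [buildGlcm()].
#' @return Named numeric vector of 24 features.
#' @export
glcmFeatures <- function(m) {
  stopifnot(m@family == "GLCM")
  glcmKernel(m@counts)
}

glcmKernel <- function(cnt) {
  ng <- nrow(cnt)
  out <- setNames(numeric(24), FEATURE_NAMES$GLCM)
  tot <- sum(cnt)
  if (tot == 0) return(out)           # single-voxel VOI: no pairs
  nz <- which(cnt > 0)
  pv <- cnt[nz] / tot
  iv <- ((nz - 1L) %% ng) + 1L
  jv <- ((nz - 1L) %/% ng) + 1L
  px <- py <- numeric(ng)
  rs <- rowsum(pv, iv)                # marginals over present levels
  px[as.integer(rownames(rs))] <- rs
  cs <- rowsum(pv, jv)
  py[as.integer(rownames(cs))] <- cs
  lev <- seq_len(ng)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  dv <- iv - jv
  av <- abs(dv)
  sv <- iv + jv

  autoc <- sum(pv * iv * jv)
  out["Autocorrelation"] <- autoc
  out["JointAverage"] <- mux
  cpl <- sv - mux - muy
  pcl2 <- pv * cpl^2
  out["ClusterProminence"] <- sum(pcl2 * cpl^2)
  out["ClusterShade"] <- sum(pv * cpl^3)
  out["ClusterTendency"] <- sum(pcl2)
  out["Contrast"] <- sum(pv * dv^2)
  out["Correlation"] <- if (sx * sy > 0) (autoc - mux * muy) / (sx * sy) else 0
  da <- sum(pv * av)
  out["DifferenceAverage"] <- da
  pm <- rowsum(pv, av)                # p_{x-y} over its support
  out["DifferenceEntropy"] <- entropy2(as.vector(pm))
  out["DifferenceVariance"] <- sum(pv * (av - da)^2)
  out["Id"] <- sum(pv / (1 + av))
  out["Idm"] <- sum(pv / (1 + av^2))
  out["Idmn"] <- sum(pv / (1 + av^2 / ng^2))
  out["Idn"] <- sum(pv / (1 + av / ng))
  hx <- entropy2(px); hy <- entropy2(py)
  hxy <- -sum(pv * log2(pv))
  lpx <- ifelse(px > 0, log2(pmax(px, 1e-300)), 0)
  lpy <- ifelse(py > 0, log2(pmax(py, 1e-300)), 0)
  hxy1 <- -sum(pv * (lpx[iv] + lpy[jv]))
  hxy2 <- hx + hy
  out["Imc1"] <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  out["Imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  off <- av > 0
  out["InverseVariance"] <- sum(pv[off] / av[off]^2)
  out["JointEnergy"] <- sum(pv^2)
  out["JointEntropy"] <- hxy
  out["MCC"] <- glcmMcc(pv, iv, jv, px, py)
  out["MaximumProbability"] <- max(pv)
  ps <- rowsum(pv, sv)                # p_{x+y} over its support
  out["SumAverage"] <- sum(pv * sv)
  out["SumEntropy"] <- entropy2(as.vector(ps))
  out["SumSquares"] <- sum(pv * (iv - mux)^2)
  out
}

# maximal correlation coefficient: sqrt of the second-largest eigenvalue of
# Q(a,b) = sum_k p(a,k) p(b,k) / (px(a) py(k)). Q = D^-1 S with S symmetric,
# so the spectrum comes from the symmetric D^-1/2 S D^-1/2, assembled on the
# present-level submatrix.
glcmMcc <- function(pv, iv, jv, px, py) {
  keep <- which(px > 0)
  k <- length(keep)
  if (k < 2L) return(1)
  pos <- integer(length(px))
  pos[keep] <- seq_len(k)
  ps <- matrix(0, k, k)
  ps[cbind(pos[iv], pos[jv])] <- pv
  pxk <- px[keep]; pyk <- py[keep]
  s <- ps %*% (t(ps) / pyk)
  cmat <- s / sqrt(outer(pxk, pxk))
  ev <- eigen((cmat + t(cmat)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  sqrt(max(0, ev[2]))
}

#' Features of a gray-level dependence matrix
#'
#' @param m a GLDM [TextureMatrix-class] from [buildGldm()].
#' @return Named numeric vector of 14 features.
#' @export
gldmFeatures <- function(m) {
  stopifnot(m@family == "GLDM")
  gldmKernel(m@counts)
}

gldmKernel <- function(cnt) {
  sp <- sparseCounts(cnt)
  out <- setNames(numeric(14), FEATURE_NAMES$GLDM)
  out["DependenceEntropy"] <- entropy2(sp$pv)
  out["DependenceNonUniformity"] <- sp$colSq / sp$tot
  out["DependenceNonUniformityNormalized"] <- sp$colSq / sp$tot^2
  out["DependenceVariance"] <- sp$varJ
  out["GrayLevelNonUniformity"] <- sp$rowSq / sp$tot
  out["GrayLevelVariance"] <- sp$varI
  out["HighGrayLevelEmphasis"] <- sum(sp$pv * sp$iv^2)
  out["LargeDependenceEmphasis"] <- sum(sp$pv * sp$jv^2)
  out["LargeDependenceHighGrayLevelEmphasis"] <-
    sum(sp$pv * sp$iv^2 * sp$jv^2)
  out["LargeDependenceLowGrayLevelEmphasis"] <-
    sum(sp$pv * sp$jv^2 / sp$iv^2)
  out["LowGrayLevelEmphasis"] <- sum(sp$pv / sp$iv^2)
  out["SmallDependenceEmphasis"] <- sum(sp$pv / sp$jv^2)
  out["SmallDependenceHighGrayLevelEmphasis"] <-
    sum(sp$pv * sp$iv^2 / sp$jv^2)
  out["SmallDependenceLowGrayLevelEmphasis"] <-
    sum(sp$pv / (sp$iv^2 * sp$jv^2))
  out
}

# shared sparse summaries of a (gray level x size-like index) count matrix:
# nonzero entries, their probabilities, marginal squared sums and the
# marginal variances over the 1-based row/column values
sparseCounts <- function(cnt) {
  tot <- sum(cnt)
  ng <- nrow(cnt)
  nz <- which(cnt > 0)
  cv <- cnt[nz]
  iv <- ((nz - 1L) %% ng) + 1L
  jv <- ((nz - 1L) %/% ng) + 1L
  pv <- cv / tot
  ri <- rowsum(pv, iv); rj <- rowsum(pv, jv)
  vi <- as.integer(rownames(ri)); vj <- as.integer(rownames(rj))
  mui <- sum(vi * ri); muj <- sum(vj * rj)
  list(tot = tot, cv = cv, pv = pv, iv = iv, jv = jv,
       rowSq = sum((ri * tot)^2), colSq = sum((rj * tot)^2),
       varI = sum((vi - mui)^2 * ri), varJ = sum((vj - muj)^2 * rj))
}

#' Features of a gray-level run-length matrix
#'
#' Run percentage is normalized by `nVoxels * 13` so that it stays in (0, 1]
#' for the merged-direction matrix (each voxel belongs to exactly one run per
#' direction).
#'
#' @param m a GLRLM [TextureMatrix-class] from [buildGlrlm()].
#' @return Named numeric vector of 16 features.
#' @export
glrlmFeatures <- function(m) {
  stopifnot(m@family == "GLRLM")
  glrlmKernel(m@counts, m@nVoxels, m@aux$nDirections)
}

glrlmKernel <- function(cnt, nVoxels, nDirections) {
  sp <- sparseCounts(cnt)
  out <- setNames(numeric(16), FEATURE_NAMES$GLRLM)
  out["GrayLevelNonUniformity"] <- sp$rowSq / sp$tot
  out["GrayLevelNonUniformityNormalized"] <- sp$rowSq / sp$tot^2
  out["GrayLevelVariance"] <- sp$varI
  out["HighGrayLevelRunEmphasis"] <- sum(sp$pv * sp$iv^2)
  out["LongRunEmphasis"] <- sum(sp$pv * sp$jv^2)
  out["LongRunHighGrayLevelEmphasis"] <- sum(sp$pv * sp$iv^2 * sp$jv^2)
  out["LongRunLowGrayLevelEmphasis"] <- sum(sp$pv * sp$jv^2 / sp$iv^2)
  out["LowGrayLevelRunEmphasis"] <- sum(sp$pv / sp$iv^2)
  out["RunEntropy"] <- entropy2(sp$pv)
  out["RunLengthNonUniformity"] <- sp$colSq / sp$tot
  out["RunLengthNonUniformityNormalized"] <- sp$colSq / sp$tot^2
  out["RunPercentage"] <- sp$tot / (nVoxels * nDirections)
  out["RunVariance"] <- sp$varJ
  out["ShortRunEmphasis"] <- sum(sp$pv / sp$jv^2)
  out["ShortRunHighGrayLevelEmphasis"] <- sum(sp$pv * sp$iv^2 / sp$jv^2)
  out["ShortRunLowGrayLevelEmphasis"] <- sum(sp$pv / (sp$iv^2 * sp$jv^2))
  out
}

#' Features of a gray-level size-zone matrix
#'
#' @param m a GLSZM [TextureMatrix-class] from [buildGlszm()].
#' @return Named numeric vector of 16 features.
#' @export
glszmFeatures <- function(m) {
  stopifnot(m@family == "GLSZM")
  glszmKernel(m@counts, m@nVoxels)
}

glszmKernel <- function(cnt, nVoxels) {
  sp <- sparseCounts(cnt)
  out <- setNames(numeric(16), FEATURE_NAMES$GLSZM)
  out["GrayLevelNonUniformity"] <- sp$rowSq / sp$tot
  out["GrayLevelNonUniformityNormalized"] <- sp$rowSq / sp$tot^2
  out["GrayLevelVariance"] <- sp$varI
  out["HighGrayLevelZoneEmphasis"] <- sum(sp$pv * sp$iv^2)
  out["LargeAreaEmphasis"] <- sum(sp$pv * sp$jv^2)
  out["LargeAreaHighGrayLevelEmphasis"] <- sum(sp$pv * sp$iv^2 * sp$jv^2)
  out["LargeAreaLowGrayLevelEmphasis"] <- sum(sp$pv * sp$jv^2 / sp$iv^2)
  out["LowGrayLevelZoneEmphasis"] <- sum(sp$pv / sp$iv^2)
  out["SizeZoneNonUniformity"] <- sp$colSq / sp$tot
  out["SizeZoneNonUniformityNormalized"] <- sp$colSq / sp$tot^2
  out["SmallAreaEmphasis"] <- sum(sp$pv / sp$jv^2)
  out["SmallAreaHighGrayLevelEmphasis"] <- sum(sp$pv * sp$iv^2 / sp$jv^2)
  out["SmallAreaLowGrayLevelEmphasis"] <-
    sum(sp$pv / (sp$iv^2 * sp$jv^2))
  out["ZoneEntropy"] <- entropy2(sp$pv)
  out["ZonePercentage"] <- sp$tot / nVoxels
  out["ZoneVariance"] <- sp$varJ
  out
}

#' Features of a neighborhood gray-tone difference matrix
#'
#' Degenerate conventions: Coarseness is capped at `1e6` when every
#' gray-tone difference is zero (perfectly flat region); Busyness and
#' Strength are 0 when their denominators vanish; Contrast is 0 when a
#' single gray level occurs.
#'
#' @param m an NGTDM [TextureMatrix-class] from [buildNgtdm()].
#' @return Named numeric vector of 5 features.
#' @export
ngtdmFeatures <- function(m) {
  stopifnot(m@family == "NGTDM")
  ngtdmKernel(as.vector(m@counts), m@aux$n)
}

ngtdmKernel <- function(s, n) {
  nvp <- sum(n)
  out <- setNames(numeric(5), FEATURE_NAMES$NGTDM)
  if (nvp == 0) {                      # all voxels isolated
    out["Coarseness"] <- 1e6
    return(out)
  }
  p <- n / nvp
  iv <- seq_along(p)
  pres <- which(p > 0)
  ngp <- length(pres)
  pi <- p[pres]; si <- s[pres]; ii <- iv[pres]
  dmat <- outer(ii, ii, "-")
  psum <- outer(pi, pi, "+")
  out["Coarseness"] <- if (sum(p * s) > 0) 1 / sum(p * s) else 1e6
  out["Contrast"] <- if (ngp > 1)
    sum(outer(pi, pi) * dmat^2) / (ngp * (ngp - 1)) * sum(si) / nvp else 0
  busyDen <- sum(abs(outer(ii * pi, ii * pi, "-")))
  out["Busyness"] <- if (busyDen > 0) sum(p * s) / busyDen else 0
  out["Complexity"] <-
    sum(abs(dmat) * (outer(pi * si, pi * si, "+") / psum)) / nvp
  out["Strength"] <- if (sum(si) > 0) sum(psum * dmat^2) / sum(si) else 0
  out
}

#' First-order intensity statistics of a VOI
#'
#' Seventeen of the eighteen first-order features are computed on the raw
#' SUV intensities (quantile convention: linear interpolation, R type 7;
#' variance, skewness and kurtosis use the population convention, kurtosis
#' not excess-corrected). Entropy and Uniformity are histogram statistics
#' and use the quantized gray levels supplied via `q`. With zero variance,
#' Skewness and Kurtosis are defined as 0.
#'
#' @param voi a [Voi-class].
#' @param q optional [QuantizedVoi-class] giving the gray levels for Entropy
#'   and Uniformity; default is the bin-width-1 discretization of `voi`.
#' @param duplicateEntropy if `TRUE`, report Entropy twice instead of the
#'   interquartile range as feature 80's value.
#' @return Named numeric vector of 18 features.
#' @export
firstOrderFeatures <- function(voi, q = NULL, duplicateEntropy = FALSE) {
  x <- voi@intensities
  if (!length(x)) stopf("empty VOI")
  if (is.null(q)) q <- discretize(voi)
  firstOrderKernel(x, q@levels, q@nLevels, prod(voi@voxelSizeMm),
                   duplicateEntropy)
}

firstOrderKernel <- function(x, levels, nLevels, voxelVolume,
                             duplicateEntropy = FALSE) {
  nm <- FEATURE_NAMES$FIRSTORDER
  if (duplicateEntropy) nm[5] <- "Entropy2"
  out <- setNames(numeric(18), nm)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  qq <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  plev <- tabulate(levels + 1L, nbins = nLevels) / n
  ent <- entropy2(plev)
  out["Percentile10"] <- qq[1]
  out["Percentile90"] <- qq[4]
  out["Energy"] <- sum(x^2)
  out["Entropy"] <- ent
  out[5] <- if (duplicateEntropy) ent else qq[3] - qq[2]
  out["Kurtosis"] <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  out["MeanAbsoluteDeviation"] <- mean(abs(x - mu))
  out["Mean"] <- mu
  out["Median"] <- median(x)
  rob <- x[x >= qq[1] & x <= qq[4]]
  out["RobustMeanAbsoluteDeviation"] <- mean(abs(rob - mean(rob)))
  out["RootMeanSquared"] <- sqrt(mean(x^2))
  out["Skewness"] <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  out["TotalEnergy"] <- voxelVolume * sum(x^2)
  out["Uniformity"] <- sum(plev^2)
  out["Variance"] <- m2
  out["Maximum"] <- max(x)
  out["Minimum"] <- min(x)
  out["Range"] <- max(x) - min(x)
  out
}

# the 93-vector at one bin width, in registry id order; works from the raw
# level array to keep the per-(VOI, width) cost low in cohort runs
batteryKernel <- function(arr, lev, nl, x, voxelVolume,
                          duplicateEntropy = FALSE) {
  n <- length(lev)
  ngt <- .cppNgtdm(arr, nl)
  c(gldmKernel(.cppGldm(arr, nl, 0L)),
    glszmKernel(zonesToCounts(.cppGlszmZones(arr), nl), n),
    glcmKernel(.cppGlcm(arr, nl)),
    ngtdmKernel(ngt[, 2], ngt[, 1]),
    glrlmKernel(.cppGlrlm(arr, nl), n, 13L),
    firstOrderKernel(x, lev, nl, voxelVolume, duplicateEntropy))
}

featureVector <- function(q, duplicateEntropy = FALSE) {
  batteryKernel(voiLevelArray(q), q@levels, q@nLevels, q@intensities,
                prod(q@voxelSizeMm), duplicateEntropy)
}

#' Extract the full feature battery from a VOI
#'
#' Discretizes the VOI to 256 gray levels, rebins to each requested bin
#' width, and computes the 93-feature battery at each width: 14 GLDM, 16
#' GLSZM, 24 GLCM, 5 NGTDM, 16 GLRLM and 18 first-order features.
#'
#' @param voi a [Voi-class].
#' @param widths bin widths to evaluate, a subset of
#'   `c(1, 2, 8, 16, 32, 64, 128)`.
#' @param duplicateEntropy see [featureRegistry()].
#' @return Long-format data.frame with columns `subject_id`, `region`,
#'   `feature_id`, `feature_name`, `family`, `bin_width`, `value`; exactly
#'   93 rows per width.
#' @export
extractFeatures <- function(voi, widths = ALLOWED_BIN_WIDTHS,
                            duplicateEntropy = FALSE) {
  if (!all(widths %in% ALLOWED_BIN_WIDTHS))
    stopf("widths must be a subset of {%s}",
          paste(ALLOWED_BIN_WIDTHS, collapse = ","))
  reg <- featureRegistry(duplicateEntropy)
  q1 <- discretize(voi)
  co <- voi@coords
  lo <- c(min(co[, 1]), min(co[, 2]), min(co[, 3]))
  d <- c(max(co[, 1]), max(co[, 2]), max(co[, 3])) - lo + 1L
  pos <- 1L + (co[, 1] - lo[1]) +
    d[1] * ((co[, 2] - lo[2]) + d[2] * (co[, 3] - lo[3]))
  template <- array(NA_integer_, dim = d)
  voxelVolume <- prod(voi@voxelSizeMm)
  ws <- sort(as.integer(widths))
  vals <- vapply(ws, function(w) {
    nl <- as.integer(ceiling(N_GRAY_LEVELS / w))
    lev <- q1@levels %/% w
    arr <- template
    arr[pos] <- lev
    v <- batteryKernel(arr, lev, nl, voi@intensities, voxelVolume,
                       duplicateEntropy)
    if (!all(is.finite(v)))
      stopf("non-finite feature value at width %d: %s", w,
            paste(names(v)[!is.finite(v)], collapse = ", "))
    unname(v)
  }, numeric(93L))
  data.frame(subject_id = voi@subject, region = voi@regionLabel,
             feature_id = rep(reg$id, length(ws)),
             feature_name = rep(reg$name, length(ws)),
             family = rep(reg$family, length(ws)),
             bin_width = rep(ws, each = 93L),
             value = as.vector(vals),
             stringsAsFactors = FALSE)
}
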